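// Compiled kernels: pairwise statistics, SARF annealing, blocked Gibbs.
//
// Conventions: marker indices are 0-based in every exported function here;
// the R wrappers convert.  Origin/chromatid states are 0 (A) and 1 (B),
// NA_INTEGER = undeterminable.  All randomness uses R's RNG stream.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------- pairwise

// Modified independence LOD for every marker pair: Pearson X^2 of the
// genotype-class contingency table divided by 2 ln 10, zero-expectation
// cells dropped.  calls: markers x offspring, class indices 1..k or NA.
// [[Rcpp::export]]
NumericMatrix pairwise_lod_cpp(IntegerMatrix calls, IntegerVector nclass) {
  const int M = calls.nrow(), N = calls.ncol();
  NumericMatrix lod(M, M);
  const double two_ln10 = 2.0 * std::log(10.0);
  std::vector<int> tab(16);
  for (int i = 0; i < M; ++i) {
    const int ki = nclass[i];
    for (int j = i + 1; j < M; ++j) {
      const int kj = nclass[j];
      std::fill(tab.begin(), tab.begin() + ki * kj, 0);
      int n = 0;
      for (int o = 0; o < N; ++o) {
        int a = calls(i, o), b = calls(j, o);
        if (a == NA_INTEGER || b == NA_INTEGER) continue;
        ++tab[(a - 1) * kj + (b - 1)];
        ++n;
      }
      double x2 = 0.0;
      if (n > 0) {
        std::vector<int> rt(ki, 0), ct(kj, 0);
        for (int a = 0; a < ki; ++a)
          for (int b = 0; b < kj; ++b) {
            rt[a] += tab[a * kj + b];
            ct[b] += tab[a * kj + b];
          }
        for (int a = 0; a < ki; ++a)
          for (int b = 0; b < kj; ++b) {
            double e = (double)rt[a] * ct[b] / n;
            if (e > 0) {
              double d = tab[a * kj + b] - e;
              x2 += d * d / e;
            }
          }
      }
      lod(i, j) = lod(j, i) = x2 / two_ln10;
    }
  }
  return lod;
}

// Pairwise recombination evidence from a chromatid-origin matrix
// (markers x offspring, 0/1/NA): per pair, the number of discordant and of
// jointly determinable meioses.
// [[Rcpp::export]]
List pairwise_rec_cpp(IntegerMatrix orig) {
  const int M = orig.nrow(), N = orig.ncol();
  IntegerMatrix nrec(M, M), ntot(M, M);
  for (int i = 0; i < M; ++i)
    for (int j = i + 1; j < M; ++j) {
      int r = 0, t = 0;
      for (int o = 0; o < N; ++o) {
        int a = orig(i, o), b = orig(j, o);
        if (a == NA_INTEGER || b == NA_INTEGER) continue;
        ++t;
        if (a != b) ++r;
      }
      nrec(i, j) = nrec(j, i) = r;
      ntot(i, j) = ntot(j, i) = t;
    }
  return List::create(_["nrec"] = nrec, _["ntot"] = ntot);
}

// ------------------------------------------------------------------- SARF

// Sum of adjacent r over one parent's sub-order (markers informative in
// that parent, in map order).
static double sarf_one(const std::vector<int>& ord, const NumericMatrix& r,
                       const LogicalVector& inf) {
  double s = 0.0;
  int prev = -1;
  for (size_t k = 0; k < ord.size(); ++k) {
    int x = ord[k];
    if (!inf[x]) continue;
    if (prev >= 0) s += r(prev, x);
    prev = x;
  }
  return s;
}

static double sarf_full(const std::vector<int>& ord,
                        const NumericMatrix& rm, const NumericMatrix& rp,
                        const LogicalVector& infm,
                        const LogicalVector& infp) {
  return sarf_one(ord, rm, infm) + sarf_one(ord, rp, infp);
}

// [[Rcpp::export]]
double sarf_cpp(IntegerVector order, NumericMatrix rm, NumericMatrix rp,
                LogicalVector infm, LogicalVector infp) {
  std::vector<int> ord(order.begin(), order.end());
  return sarf_full(ord, rm, rp, infm, infp);
}

// position t of the order *after removing index i* -> original index
static inline int orig_idx(int t, int i) { return t < i ? t : t + 1; }

// SARF change in one parent for moving marker x from position i to final
// position s (slot in the removed order).
static double move_delta_one(const std::vector<int>& ord, int i, int s,
                             const NumericMatrix& r,
                             const LogicalVector& inf) {
  const int x = ord[i];
  if (!inf[x]) return 0.0;
  const int n = (int)ord.size();
  double d = 0.0;
  // removal: former informative neighbours of x
  int p1 = -1, n1 = -1;
  for (int t = i - 1; t >= 0; --t)
    if (inf[ord[t]]) { p1 = ord[t]; break; }
  for (int t = i + 1; t < n; ++t)
    if (inf[ord[t]]) { n1 = ord[t]; break; }
  if (p1 >= 0) d -= r(p1, x);
  if (n1 >= 0) d -= r(x, n1);
  if (p1 >= 0 && n1 >= 0) d += r(p1, n1);
  // insertion: informative neighbours around slot s in the removed order
  int p2 = -1, n2 = -1;
  for (int t = s - 1; t >= 0; --t) {
    int y = ord[orig_idx(t, i)];
    if (inf[y]) { p2 = y; break; }
  }
  for (int t = s; t <= n - 2; ++t) {
    int y = ord[orig_idx(t, i)];
    if (inf[y]) { n2 = y; break; }
  }
  if (p2 >= 0) d += r(p2, x);
  if (n2 >= 0) d += r(x, n2);
  if (p2 >= 0 && n2 >= 0) d -= r(p2, n2);
  return d;
}

static double move_delta(const std::vector<int>& ord, int i, int s,
                         const NumericMatrix& rm, const NumericMatrix& rp,
                         const LogicalVector& infm,
                         const LogicalVector& infp) {
  return move_delta_one(ord, i, s, rm, infm) +
         move_delta_one(ord, i, s, rp, infp);
}

// SARF change for reversing the segment ord[i..j]: internal adjacencies
// are preserved (r is symmetric); only the boundary edges of each
// parent's sub-order change.
static double rev_delta_one(const std::vector<int>& ord, int i, int j,
                            const NumericMatrix& r,
                            const LogicalVector& inf) {
  int f1 = -1, fk = -1;
  for (int t = i; t <= j; ++t) if (inf[ord[t]]) { f1 = ord[t]; break; }
  if (f1 < 0) return 0.0;
  for (int t = j; t >= i; --t) if (inf[ord[t]]) { fk = ord[t]; break; }
  int a = -1, b = -1;
  for (int t = i - 1; t >= 0; --t) if (inf[ord[t]]) { a = ord[t]; break; }
  for (int t = j + 1; t < (int)ord.size(); ++t)
    if (inf[ord[t]]) { b = ord[t]; break; }
  double d = 0.0;
  if (a >= 0) d += r(a, fk) - r(a, f1);
  if (b >= 0) d += r(f1, b) - r(fk, b);
  return d;
}

static double rev_delta(const std::vector<int>& ord, int i, int j,
                        const NumericMatrix& rm, const NumericMatrix& rp,
                        const LogicalVector& infm,
                        const LogicalVector& infp) {
  return rev_delta_one(ord, i, j, rm, infm) +
         rev_delta_one(ord, i, j, rp, infp);
}

// Simulated annealing on SARF.  Proposals mix single-locus relocation
// (place a random locus into a random position, restricted to +/- window
// of its current position when window > 0) with segment reversal, which
// repairs misplaced blocks that locus relocation cannot reach.
// Metropolis acceptance: always if delta <= 0, else with probability
// exp(-delta / c); c cools by `cooling` per temperature level of
// `moves_per_temp` proposals.  Stops after `stop_rejections` consecutive
// rejections, or once c has decayed below c_min and two successive
// levels brought no strict improvement of the best SARF.
// When window > 0, the search is anchored to a reference seriation:
// relocation targets stay within +/- window of the marker's reference
// slot (ref_rank) and reversal segments are at most window long, so no
// marker can drift far from the reference order.
// [[Rcpp::export]]
List anneal_cpp(IntegerVector order0, NumericMatrix rm, NumericMatrix rp,
                LogicalVector infm, LogicalVector infp,
                double c0, double cooling, int moves_per_temp,
                int stop_rejections, int max_temps, double c_min,
                int window, IntegerVector ref_rank) {
  std::vector<int> ord(order0.begin(), order0.end());
  const int n = (int)ord.size();
  double cur = sarf_full(ord, rm, rp, infm, infp);
  double best = cur;
  std::vector<int> best_ord = ord;
  if (n >= 3) {
    double c = c0;
    int consec_rej = 0, stale = 0;
    bool done = false;
    for (int temp = 0; temp < max_temps && !done; ++temp) {
      bool improved = false;
      for (int mv = 0; mv < moves_per_temp; ++mv) {
        bool reversal = unif_rand() < 0.5;
        int i = (int)(unif_rand() * n); if (i >= n) i = n - 1;
        int s;
        if (reversal) {
          if (window > 0) {
            int len = 1 + (int)(unif_rand() * window);
            s = i + len; if (s > n - 1) s = n - 1;
          } else {
            s = (int)(unif_rand() * n); if (s >= n) s = n - 1;
            if (s < i) std::swap(i, s);
          }
        } else if (window > 0) {
          int base = ref_rank[ord[i]];
          int lo = base - window; if (lo < 0) lo = 0;
          int hi = base + window; if (hi > n - 1) hi = n - 1;
          s = lo + (int)(unif_rand() * (hi - lo + 1));
          if (s > hi) s = hi;
        } else {
          s = (int)(unif_rand() * n); if (s >= n) s = n - 1;
        }
        if (i == s) continue;
        double d = reversal ?
          rev_delta(ord, i, s, rm, rp, infm, infp) :
          move_delta(ord, i, s, rm, rp, infm, infp);
        bool acc = d <= 0.0 ||
          (c > 1e-12 && unif_rand() < std::exp(-d / c));
        if (acc) {
          if (reversal) {
            std::reverse(ord.begin() + i, ord.begin() + s + 1);
          } else {
            int x = ord[i];
            ord.erase(ord.begin() + i);
            ord.insert(ord.begin() + s, x);
          }
          cur += d;
          consec_rej = 0;
          if (cur < best - 1e-12) {
            best = cur; best_ord = ord; improved = true;
          }
        } else if (++consec_rej >= stop_rejections) {
          done = true; break;
        }
      }
      cur = sarf_full(ord, rm, rp, infm, infp);   // kill FP drift
      if (cur < best - 1e-12) { best = cur; best_ord = ord; }
      stale = improved ? 0 : stale + 1;
      if (stale >= 2 && c <= c_min) break;
      c *= cooling;
    }
  }
  best = sarf_full(best_ord, rm, rp, infm, infp);
  return List::create(_["order"] = IntegerVector(best_ord.begin(),
                                                 best_ord.end()),
                      _["sarf"] = best);
}

// SARF change for inserting marker x at slot s of ord (no removal).
static double ins_delta_one(const std::vector<int>& ord, int s, int x,
                            const NumericMatrix& r,
                            const LogicalVector& inf) {
  if (!inf[x]) return 0.0;
  int p = -1, nn = -1;
  for (int t = s - 1; t >= 0; --t)
    if (inf[ord[t]]) { p = ord[t]; break; }
  for (int t = s; t < (int)ord.size(); ++t)
    if (inf[ord[t]]) { nn = ord[t]; break; }
  double d = 0.0;
  if (p >= 0) d += r(p, x);
  if (nn >= 0) d += r(x, nn);
  if (p >= 0 && nn >= 0) d -= r(p, nn);
  return d;
}

// Greedy sequential insertion of new markers at their minimum-SARF slot.
// [[Rcpp::export]]
IntegerVector greedy_insert_cpp(IntegerVector order, IntegerVector newm,
                                NumericMatrix rm, NumericMatrix rp,
                                LogicalVector infm, LogicalVector infp) {
  std::vector<int> ord(order.begin(), order.end());
  for (int k = 0; k < newm.size(); ++k) {
    int x = newm[k];
    int best_s = 0;
    double best_d = R_PosInf;
    for (int s = 0; s <= (int)ord.size(); ++s) {
      double d = ins_delta_one(ord, s, x, rm, infm) +
                 ins_delta_one(ord, s, x, rp, infp);
      if (d < best_d) { best_d = d; best_s = s; }
    }
    ord.insert(ord.begin() + best_s, x);
  }
  return IntegerVector(ord.begin(), ord.end());
}

// ------------------------------------------------------------------ Gibbs

// Blocked Gibbs sampler for one parental meiosis.  obs: markers x
// offspring matrix of observed chromatid origins (0/1/NA) for the markers
// of this parent's map, in map order.  Alternates (a) exact joint sampling
// of each offspring's complete inheritance vector by forward filtering /
// backward sampling given current interval r's, and (b) a Beta(0.5 + k,
// 0.5 + m - k) draw of each interval r given the sampled crossover count k
// among m meioses (Jeffreys prior).  Returns post-burn-in r draws and the
// posterior mean origin (probability of chromatid B) per cell.
// [[Rcpp::export]]
List gibbs_chain_cpp(IntegerMatrix obs, NumericVector r_init,
                     int n_cycles, int burn_in,
                     double r_min, double r_max, double prior_a) {
  const int M = obs.nrow(), N = obs.ncol();
  const int K = M - 1;
  const int kept = n_cycles - burn_in;
  if (kept < 1) stop("n_cycles must exceed burn_in");
  std::vector<double> r(r_init.begin(), r_init.end());
  for (int j = 0; j < K; ++j)
    r[j] = std::min(std::max(r[j], r_min), r_max);
  NumericMatrix r_draws(kept, std::max(K, 0));
  NumericVector k_mean(std::max(K, 0));
  NumericMatrix orig_prob(M, N);
  std::vector<double> a0(M), a1(M);
  std::vector<int> x(M), kcount(std::max(K, 0));
  for (int cyc = 0; cyc < n_cycles; ++cyc) {
    std::fill(kcount.begin(), kcount.end(), 0);
    for (int o = 0; o < N; ++o) {
      // forward filtering (normalized)
      for (int m = 0; m < M; ++m) {
        double t0, t1;
        if (m == 0) { t0 = 0.5; t1 = 0.5; }
        else {
          double rr = r[m - 1];
          t0 = a0[m - 1] * (1 - rr) + a1[m - 1] * rr;
          t1 = a0[m - 1] * rr + a1[m - 1] * (1 - rr);
        }
        int ob = obs(m, o);
        if (ob == 0) t1 = 0.0;
        else if (ob == 1) t0 = 0.0;
        double s = t0 + t1;
        if (s <= 0) { t0 = t1 = 0.5; s = 1.0; }   // unreachable guard
        a0[m] = t0 / s; a1[m] = t1 / s;
      }
      // backward sampling
      x[M - 1] = (unif_rand() < a1[M - 1]) ? 1 : 0;
      for (int m = M - 2; m >= 0; --m) {
        double rr = r[m];
        double w0 = a0[m] * (x[m + 1] == 0 ? (1 - rr) : rr);
        double w1 = a1[m] * (x[m + 1] == 1 ? (1 - rr) : rr);
        x[m] = (unif_rand() * (w0 + w1) < w1) ? 1 : 0;
        if (x[m] != x[m + 1]) ++kcount[m];
      }
      if (cyc >= burn_in)
        for (int m = 0; m < M; ++m) orig_prob(m, o) += x[m];
    }
    for (int j = 0; j < K; ++j) {
      double rr = R::rbeta(prior_a + kcount[j], prior_a + N - kcount[j]);
      r[j] = std::min(std::max(rr, r_min), r_max);
      if (cyc >= burn_in) {
        r_draws(cyc - burn_in, j) = r[j];
        k_mean[j] += kcount[j];
      }
    }
  }
  for (int m = 0; m < M; ++m)
    for (int o = 0; o < N; ++o) orig_prob(m, o) /= kept;
  for (int j = 0; j < K; ++j) k_mean[j] /= kept;
  return List::create(_["r_draws"] = r_draws,
                      _["k_mean"] = k_mean,
                      _["origin_prob"] = orig_prob);
}
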