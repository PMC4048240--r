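# Two-point analysis for CP segregation-type pairs and linkage-phase
# inference by anchoring.

# Joint genotype-class probability table for a marker pair.  The engine
# enumerates the four chromatid transmissions of each meiosis with
# probabilities {1-r, r} and maps them to observable classes; this covers
# all segregation-type combinations without hand-coded tables.  Phases of
# marker i are fixed to coupling; `phase_pair` holds the relative phases
# (maternal, paternal) of marker j.
pair_class_probs <- function(code_i, code_j, phase_pair, r) {
  lut <- pair_lut(code_i, code_j, phase_pair)
  w <- c((1 - r)^2, r * (1 - r), r * (1 - r), r^2)   # by recombination type
  P <- matrix(0, lut$ki, lut$kj)
  for (t in seq_len(nrow(lut$map)))
    P[lut$map[t, 1], lut$map[t, 2]] <-
      P[lut$map[t, 1], lut$map[t, 2]] + 0.25 * w[lut$map[t, 3]]
  dimnames(P) <- lut$dn
  P
}

# cached transmission lookup: rows (class_i, class_j, type) with type
# 1..4 = (maternal rec?, paternal rec?) in {no/no, yes/no, no/yes, yes/yes}
.pair_lut_cache <- new.env(parent = emptyenv())
pair_lut <- function(code_i, code_j, phase_pair) {
  key <- paste(code_i, code_j, phase_pair[1], phase_pair[2], sep = "|")
  hit <- .pair_lut_cache[[key]]
  if (!is.null(hit)) return(hit)
  sti <- seg_type(code_i); stj <- seg_type(code_j)
  map <- matrix(0L, 16, 3)
  t <- 0L
  for (oim in 0:1) for (ojm in 0:1) for (oip in 0:1) for (ojp in 0:1) {
    t <- t + 1L
    map[t, 1] <- class_from_origins(oim, oip, code_i, 0L, 0L)
    map[t, 2] <- class_from_origins(ojm, ojp, code_j,
                                    phase_pair[1], phase_pair[2])
    map[t, 3] <- 1L + (oim != ojm) + 2L * (oip != ojp)
  }
  res <- list(map = map, ki = length(sti$classes),
              kj = length(stj$classes),
              dn = list(sti$classes, stj$classes))
  .pair_lut_cache[[key]] <- res
  res
}

#' Two-point log-likelihood of a marker pair
#'
#' Multinomial log-likelihood of the observed joint genotype-class counts
#' under the class-probability table implied by the two segregation types,
#' the relative phases, and a common recombination fraction `r` for both
#' meioses.
#'
#' @param counts joint class-count matrix (see [pair_contingency()]).
#' @param code_i,code_j segregation codes of the two markers.
#' @param phase_pair integer vector `c(maternal, paternal)` of relative
#'   phases of marker j versus marker i (0 coupling / 1 repulsion).
#' @param r recombination fraction in `(0, 0.5]`.
#' @return log-likelihood value.
#' @export
pair_likelihood <- function(counts, code_i, code_j,
                            phase_pair = c(0L, 0L), r) {
  if (r <= 0 || r > 0.5) stop("r must be in (0, 0.5]", call. = FALSE)
  P <- pair_class_probs(code_i, code_j, phase_pair, r)
  use <- counts > 0
  if (any(use & P <= 0)) return(-Inf)
  sum(counts[use] * log(P[use]))
}

#' Two-point estimate for one marker pair
#'
#' Maximizes [pair_likelihood()] over `r` for each admissible relative
#' phase combination (phases only matter for parents in which both markers
#' are informative) and returns the best phase pair, the maximum-likelihood
#' recombination fraction, and the base-10 LOD against independence (r of 0.5).
#'
#' @param calls_i,calls_j class-index call vectors.
#' @param code_i,code_j segregation codes.
#' @param min_informative minimum jointly observed offspring (default 20);
#'   below it the pair is reported uninformative (`NULL`).
#' @param r_min lower clamp for the estimate.
#' @return `NULL` for uninformative pairs (no shared informative parent or
#'   too few complete observations), else a list with `r`, `lod`, `phase`
#'   (named relative-phase pair), `loglik`, `n`.
#' @export
estimate_pair <- function(calls_i, calls_j, code_i, code_j,
                          min_informative = 20, r_min = 1e-4) {
  sti <- seg_type(code_i); stj <- seg_type(code_j)
  shared <- sti$informative & stj$informative
  if (!any(shared)) return(NULL)
  ok <- !is.na(calls_i) & !is.na(calls_j)
  if (sum(ok) < min_informative) return(NULL)
  counts <- pair_contingency(calls_i, calls_j,
                             length(sti$classes), length(stj$classes))
  ph_m <- if (shared[1]) 0:1 else 0L
  ph_p <- if (shared[2]) 0:1 else 0L
  best <- NULL
  for (pm in ph_m) for (pp in ph_p) {
    opt <- stats::optimize(
      function(r) pair_likelihood(counts, code_i, code_j, c(pm, pp), r),
      interval = c(r_min, 0.5), maximum = TRUE, tol = 1e-8)
    if (is.null(best) || opt$objective > best$loglik)
      best <- list(r = opt$maximum, loglik = opt$objective,
                   phase = c(maternal = pm, paternal = pp))
  }
  ll0 <- pair_likelihood(counts, code_i, code_j, best$phase, 0.5)
  r_hat <- min(max(best$r, r_min), 0.5)
  list(r = r_hat, lod = max(0, (best$loglik - ll0) / log(10)),
       phase = best$phase, loglik = best$loglik, n = sum(counts))
}

# Pairwise recombination evidence per parent from origins computed under
# all-coupling phases.  Returns, per parent, the discordance counts and the
# derived quantities used by phasing and ordering.
raw_pairwise <- function(geno) {
  inf <- informative_markers(geno)
  phases0 <- matrix(NA_integer_, nrow(inf), 2, dimnames = dimnames(inf))
  phases0[, 1][inf[, 1]] <- 0L
  phases0[, 2][inf[, 2]] <- 0L
  org <- origins_from_calls(geno, phases0)
  out <- list()
  for (par in c("maternal", "paternal")) {
    rec <- pairwise_rec_cpp(org[[par]])
    out[[par]] <- list(nrec = rec$nrec, ntot = rec$ntot)
  }
  out$informative <- inf
  out
}

# base-10 LOD of k recombinants in n meioses against r = 0.5
count_lod <- function(k, n, r_min = 1e-4) {
  r <- pmin(pmax(k / pmax(n, 1), r_min), 0.5)
  lod <- k * log10(r) + (n - k) * log10(1 - r) - n * log10(0.5)
  ifelse(n > 0, pmax(lod, 0), 0)
}

#' Linkage-phase inference by anchoring
#'
#' For each parent, builds a maximum-LOD spanning tree over the markers
#' informative in that parent (edges require enough jointly determinable
#' meioses and a minimum LOD), fixes an arbitrary anchor marker to
#' coupling, and propagates each pair's best relative phase along the tree.
#' Non-tree edges that disagree with the propagated phases are counted as
#' conflicts.
#'
#' @param geno an [fs_geno()] object (typically one linkage group).
#' @param min_informative minimum jointly determinable meioses for an edge.
#' @param phase_lod_min minimum pair LOD for an edge.
#' @return marker x 2 integer phase matrix (0 coupling / 1 repulsion, `NA`
#'   for uninformative parents), with attributes `conflicts` and
#'   `n_components` (named per parent).  Disconnected parents get phases
#'   per component, with a warning.
#' @export
anchor_phases <- function(geno, min_informative = 20, phase_lod_min = 1) {
  rp <- raw_pairwise(geno)
  n_mrk <- nrow(geno$calls)
  phases <- matrix(NA_integer_, n_mrk, 2,
                   dimnames = list(geno$marker_ids,
                                   c("maternal", "paternal")))
  conflicts <- c(maternal = 0L, paternal = 0L)
  ncomp <- c(maternal = 0L, paternal = 0L)
  for (par in c("maternal", "paternal")) {
    idx <- which(rp$informative[, par])
    if (!length(idx)) next
    if (length(idx) == 1L) { phases[idx, par] <- 0L; ncomp[par] <- 1L; next }
    nrec <- rp[[par]]$nrec[idx, idx, drop = FALSE]
    ntot <- rp[[par]]$ntot[idx, idx, drop = FALSE]
    f <- nrec / pmax(ntot, 1)
    rel <- f > 0.5                       # repulsion relative phase
    k <- pmin(nrec, ntot - nrec)
    lodw <- count_lod(k, ntot)
    valid <- ntot >= min_informative & lodw >= phase_lod_min
    diag(valid) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(valid, mode = "undirected")
    comp <- igraph::components(g)
    ncomp[par] <- comp$no
    if (comp$no > 1L)
      warning("phase anchoring: ", par,
              " markers form ", comp$no, " disconnected components",
              call. = FALSE)
    # maximum-LOD spanning forest
    igraph::E(g)$weight <- -lodw[igraph::as_edgelist(g, names = FALSE)]
    tree <- igraph::mst(g)
    adj <- igraph::as_adj_list(tree)
    ph <- rep(NA_integer_, length(idx))
    for (root in match(unique(comp$membership), comp$membership)) {
      if (!is.na(ph[root])) next
      ph[root] <- 0L
      queue <- root
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        for (w in as.integer(adj[[v]])) {
          if (is.na(ph[w])) {
            ph[w] <- bitwXor(ph[v], as.integer(rel[v, w]))
            queue <- c(queue, w)
          }
        }
      }
    }
    ph[is.na(ph)] <- 0L
    # conflict count over non-tree valid edges
    el <- igraph::as_edgelist(g, names = FALSE)
    tel <- igraph::as_edgelist(tree, names = FALSE)
    tkey <- paste(pmin(tel[, 1], tel[, 2]), pmax(tel[, 1], tel[, 2]))
    ekey <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
    nontree <- el[!(ekey %in% tkey), , drop = FALSE]
    if (nrow(nontree))
      conflicts[par] <- sum(bitwXor(ph[nontree[, 1]], ph[nontree[, 2]]) !=
                              as.integer(rel[nontree]))
    phases[idx, par] <- ph
  }
  structure(phases, conflicts = conflicts, n_components = ncomp)
}

# Phased pairwise matrices for ordering: per-parent recombination-fraction
# matrices (NA where evidence is insufficient) plus a pooled combined
# matrix, computed from origins under the anchored phases.
twopoint_matrices <- function(geno, phases, min_pair_n = 20,
                              r_min = 1e-4) {
  org <- origins_from_calls(geno, phases)
  out <- list()
  pooled_rec <- pooled_tot <- 0
  for (par in c("maternal", "paternal")) {
    rec <- pairwise_rec_cpp(org[[par]])
    f <- rec$nrec / pmax(rec$ntot, 1)
    r <- pmin(pmax(f, r_min), 0.5)       # phased: f > 0.5 clamps to 0.5
    r[rec$ntot < min_pair_n] <- NA
    diag(r) <- 0
    out[[par]] <- list(r = r, nrec = rec$nrec, ntot = rec$ntot)
    pooled_rec <- pooled_rec + rec$nrec
    pooled_tot <- pooled_tot + rec$ntot
  }
  r_comb <- pooled_rec / pmax(pooled_tot, 1)
  r_comb <- pmin(pmax(r_comb, r_min), 0.5)
  r_comb[pooled_tot < min_pair_n] <- NA
  diag(r_comb) <- 0

  # hkxhk pairs whose relative phase differs between the parents starve
  # the count-based estimator: linked phase-mixed pairs have far fewer
  # jointly determinable origins than the expected 25% per meiosis (a
  # homozygote at one marker implies the ambiguous hk class at the
  # other), and the cells that remain are enriched for recombinants, so
  # the discordance clamps to 0.5 exactly at true adjacencies.  Detect
  # the determinability deficit per parent and re-estimate such pairs
  # with the full multinomial two-point likelihood over all offspring.
  hk <- which(geno$seg == "hkxhk")
  if (length(hk) >= 2L) {
    obs <- !is.na(geno$calls[hk, , drop = FALSE])
    n_both <- tcrossprod(obs * 1)          # jointly observed offspring
    deficit <- matrix(FALSE, length(hk), length(hk))
    for (par in c("maternal", "paternal")) {
      ntot <- out[[par]]$ntot[hk, hk, drop = FALSE]
      deficit <- deficit | ntot < pmax(0.6 * 0.25 * n_both, min_pair_n)
    }
    idx <- which(upper.tri(deficit) & deficit, arr.ind = TRUE)
    for (s in seq_len(nrow(idx))) {
      i <- hk[idx[s, 1]]; j <- hk[idx[s, 2]]
      est <- estimate_pair(geno$calls[i, ], geno$calls[j, ],
                           "hkxhk", "hkxhk",
                           min_informative = min_pair_n, r_min = r_min)
      if (!is.null(est)) {
        for (par in c("maternal", "paternal"))
          out[[par]]$r[i, j] <- out[[par]]$r[j, i] <- est$r
        r_comb[i, j] <- r_comb[j, i] <- est$r
      }
    }
  }
  out$combined <- r_comb
  out$origins <- org
  out
}

#' Long-format export of pairwise statistics
#'
#' @param geno an [fs_geno()] object.
#' @param phases phase matrix from [anchor_phases()].
#' @param min_pair_n minimum jointly determinable meioses.
#' @return data.frame with `marker_i`, `marker_j`, `parent`, `r`, `lod`,
#'   `n` for every informative pair.
#' @export
pairwise_table <- function(geno, phases, min_pair_n = 20) {
  tp <- twopoint_matrices(geno, phases, min_pair_n)
  ids <- geno$marker_ids
  res <- list()
  for (par in c("maternal", "paternal")) {
    ntot <- tp[[par]]$ntot; nrec <- tp[[par]]$nrec
    ut <- which(upper.tri(ntot) & ntot >= min_pair_n, arr.ind = TRUE)
    if (!nrow(ut)) next
    res[[par]] <- data.frame(
      marker_i = ids[ut[, 1]], marker_j = ids[ut[, 2]], parent = par,
      r = tp[[par]]$r[ut],
      lod = count_lod(pmin(nrec[ut], ntot[ut] - nrec[ut]), ntot[ut]),
      n = ntot[ut], stringsAsFactors = FALSE)
  }
  do.call(rbind, res)
}
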