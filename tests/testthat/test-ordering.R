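# Ordering: SARF, spatial sampling, annealing, Gibbs multipoint,
# integration, group-map building.

# noiseless per-parent r matrices for markers at given positions
noiseless_r <- function(pos) {
  d <- abs(outer(pos, pos, "-"))
  cM_to_r(d)
}

test_that("SARF: closed forms, reversal invariance, brute-force equality", {
  r <- noiseless_r(c(0, 10))
  infm <- infp <- c(TRUE, TRUE)
  expect_equal(sarf(1:2, r, r, infm, infp), 2 * cM_to_r(10))
  set.seed(2)
  for (rep in 1:5) {
    n <- 7
    pos <- sort(runif(n, 0, 80))
    rm <- noiseless_r(pos) + matrix(runif(n * n, 0, 0.05), n)
    rm <- (rm + t(rm)) / 2; diag(rm) <- 0
    rp <- noiseless_r(pos)
    infm <- runif(n) < 0.7; infp <- runif(n) < 0.7
    ord <- sample(n)
    expect_equal(sarf(ord, rm, rp, infm, infp),
                 brute_sarf(ord, rm, rp, infm, infp), tolerance = 1e-12)
    expect_equal(sarf(ord, rm, rp, infm, infp),
                 sarf(rev(ord), rm, rp, infm, infp), tolerance = 1e-12)
  }
})

test_that("true order uniquely minimizes noiseless SARF (exhaustive)", {
  pos <- c(0, 10, 20, 30, 40)
  r <- noiseless_r(pos)
  inf <- rep(TRUE, 5)
  pm <- perms(5)
  vals <- apply(pm, 1, function(o) sarf(o, r, r, inf, inf))
  best <- which(vals <= min(vals) + 1e-12)
  expect_length(best, 2)                       # true order and reverse
  expect_true(all(apply(pm[best, ], 1, function(o)
    all(o == 1:5) || all(o == 5:1))))
})

test_that("annealer attains the exhaustive SARF minimum for small n", {
  set.seed(5)
  for (rep in 1:3) {
    n <- 7
    pos <- sort(runif(n, 0, 90))
    r <- noiseless_r(pos)
    inf <- rep(TRUE, n)
    pm <- perms(n)
    opt <- min(apply(pm, 1, function(o) sarf(o, r, r, inf, inf)))
    res <- anneal_order(sample(n), r, r, inf, inf)
    expect_equal(res$sarf, opt, tolerance = 1e-9)
  }
})

test_that("annealer recovers the order of 20 equally spaced markers", {
  set.seed(9)
  pos <- seq(0, 95, by = 5)
  r <- noiseless_r(pos)
  inf <- rep(TRUE, 20)
  res <- anneal_order(sample(20), r, r, inf, inf)
  expect_equal(order_correlation(res$order, pos), 1.0)
  # annealing never worsens the objective
  expect_lte(res$sarf, sarf(sample(20), r, r, inf, inf))
})

test_that("spatial sampling enforces the radius and the priority order", {
  r <- matrix(0.1, 3, 3); diag(r) <- 0
  set.seed(1)
  picked <- spatial_sample(r, 0.15, rep("abxcd", 3))
  expect_length(picked, 1L)
  # tiny radius keeps everything
  expect_length(spatial_sample(r, 1e-6, rep("abxcd", 3)), 3L)
  # post-hoc invariant on a random matrix + full-cross priority
  set.seed(12)
  n <- 40
  m <- matrix(runif(n * n, 0, 0.5), n); m <- (m + t(m)) / 2; diag(m) <- 0
  seg <- sample(SEG_CODES, n, TRUE)
  picked <- spatial_sample(m, 0.2, seg)
  if (length(picked) > 1) {
    sub <- m[picked, picked]
    expect_true(all(sub[upper.tri(sub)] >= 0.2))
  }
  expect_true(seg[picked[1]] %in%
                if (any(seg %in% c("abxcd", "efxeg")))
                  c("abxcd", "efxeg") else seg)
})

test_that("Gibbs interval estimates match count-based fractions on clean data", {
  set.seed(14)
  n_mrk <- 6; n_off <- 300
  r_true <- c(0.05, 0.1, 0.2, 0.08, 0.15)
  om <- sim_origin_chain(n_mrk, n_off, r_true)
  op <- sim_origin_chain(n_mrk, n_off, r_true)
  fam <- family_from_origins(om, op, rep("abxcd", n_mrk))
  gb <- gibbs_multipoint(1:n_mrk, fam$geno, fam$phases,
                         n_cycles = 60, burn_in = 20)
  for (par in c("maternal", "paternal")) {
    o <- if (par == "maternal") om else op
    counts <- rowSums(o[-1, ] != o[-n_mrk, ])
    r_count <- counts / n_off
    est <- gb[[par]]$interval_r
    # fully informative: the posterior concentrates on the count fraction
    expect_lt(max(abs(est - r_count)),
              3 * max(sqrt(r_count * (1 - r_count) / n_off)))
    expect_true(gb[[par]]$converged)
  }
})

test_that("all-non-recombinant data drives interval r to the floor", {
  n_off <- 200
  om <- matrix(rep(sample(0:1, n_off, TRUE), each = 5), 5)
  fam <- family_from_origins(om, om, rep("abxcd", 5))
  set.seed(3)
  gb <- gibbs_multipoint(1:5, fam$geno, fam$phases)
  expect_true(all(gb$maternal$interval_r < 0.01))
})

test_that("two independent Gibbs seeds agree within Monte-Carlo error", {
  set.seed(26)
  om <- sim_origin_chain(8, 200, rep(0.08, 7))
  op <- sim_origin_chain(8, 200, rep(0.08, 7))
  fam <- family_from_origins(om, op, rep("abxcd", 8))
  set.seed(101)
  g1 <- gibbs_multipoint(1:8, fam$geno, fam$phases, n_cycles = 50,
                         burn_in = 15)
  set.seed(202)
  g2 <- gibbs_multipoint(1:8, fam$geno, fam$phases, n_cycles = 50,
                         burn_in = 15)
  pooled <- sqrt(g1$maternal$mc_se^2 + g2$maternal$mc_se^2)
  expect_true(all(abs(g1$maternal$interval_r - g2$maternal$interval_r) <=
                    3 * pooled + 1e-3))
})

test_that("Gibbs recovers interval r on simulated 5-marker data", {
  set.seed(33)
  n_off <- 200
  om <- sim_origin_chain(5, n_off, rep(0.05, 4))
  op <- sim_origin_chain(5, n_off, rep(0.05, 4))
  fam <- family_from_origins(om, op, rep("abxcd", 5))
  gb <- gibbs_multipoint(1:5, fam$geno, fam$phases, n_cycles = 60,
                         burn_in = 20)
  ci_half <- 1.96 * sqrt(0.05 * 0.95 / n_off)
  for (par in c("maternal", "paternal"))
    expect_true(all(abs(gb[[par]]$interval_r - 0.05) <= ci_half + 0.01))
})

test_that("map integration covers every marker once and merges positions", {
  set.seed(44)
  om <- sim_origin_chain(6, 150, rep(0.1, 5))
  op <- sim_origin_chain(6, 150, rep(0.1, 5))
  # alternate full-cross and single-parent markers
  seg <- c("abxcd", "nnxnp", "hkxhk", "lmxll", "abxcd", "efxeg")
  fam <- family_from_origins(om, op, seg)
  gb <- gibbs_multipoint(1:6, fam$geno, fam$phases, n_cycles = 40,
                         burn_in = 10)
  integ <- integrate_maps(1:6, gb)
  expect_equal(sort(integ$order), 1:6)
  expect_equal(length(integ$pos_cM), 6)
  expect_true(all(diff(integ$pos_cM) >= 0))
  # identical parental orders: integrated order equals both
  expect_equal(integ$order[integ$order %in% gb$maternal$markers],
               gb$maternal$markers)
})

test_that("build_group_map perfectly orders small clean groups", {
  # 10 markers, ~11 cM spacing, 500 offspring: every adjacent pair has
  # dozens of recombinants, so the order is statistically identifiable.
  # Only one test-cross type: adjacent test-cross markers of OPPOSITE
  # parents share no meiosis and their relative order is unknowable.
  sim <- simulate_family(sim_config(n_offspring = 500, n_markers = 10,
                                    chrom_length_cM = 100,
                                    seg_type_mix = c(abxcd = 0.4,
                                                     efxeg = 0.3,
                                                     nnxnp = 0.3),
                                    seed = 55))
  ph <- anchor_phases(sim$geno)
  set.seed(7)
  map <- build_group_map(sim$geno, ph)
  expect_equal(order_correlation(map$ids,
                                 stats::setNames(sim$truth$positions$pos_cM,
                                                 sim$truth$positions$marker)),
               1.0)
  expect_true(map$converged)
  # single-marker group degenerates gracefully
  one <- fsmapr:::subset_markers(sim$geno, 1L)
  m1 <- build_group_map(one, ph[1, , drop = FALSE])
  expect_equal(m1$order, 1L)
  expect_equal(m1$pos_cM, 0)
})

test_that("order quality degrades gracefully with injected error", {
  rhos <- numeric(0)
  for (er in c(0, 0.1, 0.2)) {
    sim <- simulate_family(sim_config(n_offspring = 150, n_markers = 60,
                                      error_rate = er, seed = 61))
    ph <- anchor_phases(sim$geno)
    set.seed(8)
    map <- build_group_map(sim$geno, ph)
    rhos <- c(rhos, order_correlation(
      map$ids, stats::setNames(sim$truth$positions$pos_cM,
                               sim$truth$positions$marker)))
  }
  expect_gte(rhos[1], 0.97)
  expect_gte(min(rhos), 0.85)        # noisy but never collapsing
})
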