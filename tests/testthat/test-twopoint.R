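# Two-point analysis: pair likelihood engine, ML estimation, phase
# anchoring.

test_that("pair likelihood equals the binomial closed form for test-cross pairs", {
  tp <- testcross_pair(100, 10)
  counts <- pair_contingency(tp$calls_i, tp$calls_j, 2, 2)
  for (r in c(0.05, 0.1, 0.3)) {
    ll <- pair_likelihood(counts, "nnxnp", "nnxnp", c(0L, 0L), r)
    # closed form: 90 parental at (1-r)/2, 10 recombinant at r/2
    expect_equal(ll, 90 * log((1 - r) / 2) + 10 * log(r / 2),
                 tolerance = 1e-10)
  }
  # independence limit: uniform class probabilities
  ll <- pair_likelihood(counts, "nnxnp", "nnxnp", c(0L, 0L), 0.5)
  expect_equal(ll, sum(counts) * log(0.25), tolerance = 1e-10)
})

test_that("class-probability tables match an exhaustive transmission oracle", {
  combos <- list(c("hkxhk", "hkxhk"), c("abxcd", "efxeg"),
                 c("hkxhk", "nnxnp"), c("lmxll", "abxcd"))
  for (cmb in combos) for (pm in 0:1) for (pp in 0:1) for (r in c(0.1, 0.37)) {
    sti <- seg_type(cmb[1]); stj <- seg_type(cmb[2])
    P_oracle <- matrix(0, length(sti$classes), length(stj$classes),
                       dimnames = list(sti$classes, stj$classes))
    for (oim in 0:1) for (ojm in 0:1) for (oip in 0:1) for (ojp in 0:1) {
      pr <- 0.25 * (if (oim == ojm) 1 - r else r) *
        (if (oip == ojp) 1 - r else r)
      ci <- oracle_class(cmb[1], oim, oip, 0L, 0L)
      cj <- oracle_class(cmb[2], ojm, ojp, pm, pp)
      P_oracle[ci, cj] <- P_oracle[ci, cj] + pr
    }
    P <- fsmapr:::pair_class_probs(cmb[1], cmb[2], c(pm, pp), r)
    expect_equal(P, P_oracle, tolerance = 1e-12)
    expect_equal(sum(P), 1, tolerance = 1e-12)
  }
})

test_that("estimate_pair recovers r from direct counts", {
  # 10 recombinants in 100 -> r = 0.10
  tp <- testcross_pair(100, 10)
  est <- estimate_pair(tp$calls_i, tp$calls_j, "nnxnp", "nnxnp")
  expect_equal(est$r, 0.10, tolerance = 1e-4)
  # 0 recombinants -> r_min clamp, LOD ~ 100 log10(2)
  tp0 <- testcross_pair(100, 0)
  est0 <- estimate_pair(tp0$calls_i, tp0$calls_j, "nnxnp", "nnxnp")
  expect_lt(est0$r, 2e-4)            # clamped at the r_min floor
  expect_equal(est0$lod, 100 * log10(2), tolerance = 0.05)
  # 50 recombinants -> no linkage
  tp5 <- testcross_pair(100, 50)
  est5 <- estimate_pair(tp5$calls_i, tp5$calls_j, "nnxnp", "nnxnp")
  expect_equal(est5$r, 0.5, tolerance = 1e-3)
  expect_equal(est5$lod, 0, tolerance = 1e-6)
  # no shared informative parent -> NULL
  expect_null(estimate_pair(tp$calls_i, tp$calls_j, "nnxnp", "lmxll"))
  # too few complete observations -> NULL
  expect_null(estimate_pair(tp$calls_i[1:10], tp$calls_j[1:10],
                            "nnxnp", "nnxnp"))
})

test_that("optimizer r equals the count fraction on fully informative pairs", {
  set.seed(13)
  for (rep in 1:6) {
    n <- 150
    k <- sample(5:60, 1)
    tp <- testcross_pair(n, k)
    est <- estimate_pair(tp$calls_i, tp$calls_j, "nnxnp", "nnxnp")
    expect_equal(est$r, k / n, tolerance = 1e-6)
  }
})

test_that("r-hat is monotone in the recombinant count", {
  r_prev <- 0
  for (k in c(5, 15, 30, 45)) {
    tp <- testcross_pair(120, k)
    est <- estimate_pair(tp$calls_i, tp$calls_j, "nnxnp", "nnxnp")
    expect_gte(est$r, r_prev)
    r_prev <- est$r
  }
})

test_that("phase parity: a global flip of one parent leaves the fit unchanged", {
  # generate the same meioses under phases (0,0)/(0,0) and under a global
  # maternal flip (1,.)/(1,.): relative phases are unchanged, so the
  # maximized likelihood and r estimate must coincide
  set.seed(21)
  n <- 120
  om <- matrix(sample(0:1, 2 * n, TRUE), 2)
  op <- om
  op[2, seq_len(20)] <- 1L - op[2, seq_len(20)]   # some recombinants
  seg <- c("abxcd", "abxcd")
  f0 <- family_from_origins(om, op, seg,
                            matrix(0L, 2, 2))
  f1 <- family_from_origins(om, op, seg,
                            matrix(c(1L, 1L, 0L, 0L), 2, 2))
  e0 <- estimate_pair(f0$geno$calls[1, ], f0$geno$calls[2, ],
                      "abxcd", "abxcd")
  e1 <- estimate_pair(f1$geno$calls[1, ], f1$geno$calls[2, ],
                      "abxcd", "abxcd")
  expect_equal(e0$r, e1$r, tolerance = 1e-8)
  expect_equal(e0$loglik, e1$loglik, tolerance = 1e-8)
  expect_equal(e0$phase, e1$phase)   # relative phases unchanged
})

test_that("anchoring propagates relative phases along a repulsion chain", {
  # M1/M2 in repulsion, M2/M3 in repulsion -> M1 and M3 in coupling
  set.seed(31)
  n <- 100
  o <- sample(0:1, n, TRUE)
  calls <- rbind(o + 1L,                      # coupling reference
                 (1L - o) + 1L,               # flipped = repulsion vs M1
                 o + 1L)                      # flipped twice = coupling
  g <- fs_geno(calls, rep("nnxnp", 3))
  ph <- anchor_phases(g, min_informative = 20, phase_lod_min = 1)
  expect_true(all(is.na(ph[, "maternal"])))
  p <- unname(ph[, "paternal"])
  expect_equal(p[1], p[3])
  expect_equal(p[2], 1L - p[1])
})

test_that("anchoring recovers simulated phases up to a global flip", {
  sim <- simulate_family(sim_config(n_offspring = 150, n_markers = 60,
                                    error_rate = 0.02,
                                    missing_rate = 0.05, seed = 23))
  ph <- suppressWarnings(anchor_phases(sim$geno))
  for (p in 1:2) {
    a <- ph[, p]; b <- sim$truth$phases[, p]
    ok <- !is.na(a) & !is.na(b)
    agree <- mean(a[ok] == b[ok])
    expect_true(agree == 1 || agree == 0,
                label = sprintf("parent %d parity (agree=%.3f)", p, agree))
  }
})
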