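# Correction: singleton detection, kNN correction/imputation, suspicious
# markers.

# build a clean single-parent family where origins are directly legible
testcross_family <- function(origin_rows) {
  o <- do.call(rbind, origin_rows)
  fam <- family_from_origins(matrix(0L, nrow(o), ncol(o)), o,
                             rep("nnxnp", nrow(o)))
  fam
}

test_that("singleton definition: middles differ from both neighbours", {
  inf <- matrix(c(FALSE, TRUE), 4, 2, byrow = TRUE,
                dimnames = list(NULL, c("maternal", "paternal")))
  # one offspring, rows = markers: A A B A -> singleton at marker 3
  fam <- testcross_family(list(c(0L), c(0L), c(1L), c(0L)))
  org <- fsmapr:::origins_from_calls(fam$geno, fam$phases)
  s <- detect_singletons(org, 1:4, informative_markers(fam$geno))
  expect_equal(nrow(s), 1L)
  expect_equal(s$marker, 3L)
  expect_equal(s$parent, "paternal")
  expect_equal(s$observed, 1L)
  expect_equal(s$neighbor, 0L)
  # A A B B A A -> a double, not a singleton
  fam2 <- testcross_family(list(c(0L), c(0L), c(1L), c(1L), c(0L), c(0L)))
  org2 <- fsmapr:::origins_from_calls(fam2$geno, fam2$phases)
  expect_equal(nrow(detect_singletons(org2, 1:6,
                                      informative_markers(fam2$geno))), 0L)
  # terminal loci are never singletons: B A A A
  fam3 <- testcross_family(list(c(1L), c(0L), c(0L), c(0L)))
  org3 <- fsmapr:::origins_from_calls(fam3$geno, fam3$phases)
  expect_equal(nrow(detect_singletons(org3, 1:4,
                                      informative_markers(fam3$geno))), 0L)
})

test_that("detector equals the brute-force definition scan (property)", {
  set.seed(71)
  for (rep in 1:6) {
    n_mrk <- 30; n_off <- 25
    seg <- sample(SEG_CODES, n_mrk, TRUE)
    om <- matrix(sample(0:1, n_mrk * n_off, TRUE), n_mrk)
    op <- matrix(sample(0:1, n_mrk * n_off, TRUE), n_mrk)
    fam <- family_from_origins(om, op, seg)
    # blank some calls
    fam$geno$calls[sample(length(fam$geno$calls), 50)] <- NA_integer_
    org <- fsmapr:::origins_from_calls(fam$geno, fam$phases)
    inf <- informative_markers(fam$geno)
    ord <- sample(n_mrk)
    expect_equal(nrow(detect_singletons(org, ord, inf)),
                 brute_singletons(org, ord, inf))
  }
})

test_that("clean complete data is a no-op for knn_correct", {
  # dense map: adjacent r small enough that genuine double crossovers
  # (which legitimately look like singletons) have negligible probability
  set.seed(77)
  om <- sim_origin_chain(30, 60, rep(0.003, 29))
  op <- sim_origin_chain(30, 60, rep(0.003, 29))
  fam <- family_from_origins(om, op,
                             sample(SEG_CODES, 30, TRUE))
  res <- knn_correct(fam$geno, fam$phases, 1:30,
                     seq(0, by = 0.15, length.out = 30))
  expect_identical(res$geno$calls, fam$geno$calls)
  expect_equal(nrow(res$report$changes), 0L)
  expect_equal(res$report$n_corrected + res$report$n_imputed +
                 res$report$n_eliminated, 0L)
})

test_that("an isolated singleton is corrected to its neighbourhood origin", {
  # 9 markers, 30 offspring, no recombination; flip one cell
  n_off <- 30
  o <- matrix(0L, 9, n_off)
  fam <- testcross_family(asplit(o, 1))
  # inject: offspring 5, marker 5 becomes origin B ("np")
  calls <- fam$geno$calls
  calls[5, 5] <- 2L
  g <- fs_geno(calls, fam$geno$seg)
  res <- knn_correct(g, fam$phases, 1:9, seq(0, 40, by = 5), k = 4)
  expect_equal(res$report$n_corrected, 1L)
  expect_equal(as.integer(res$geno$calls[5, 5]), 1L)
  expect_equal(res$report$changes$reason, "corrected")
  # correction never increases the singleton count
  org_pre <- fsmapr:::origins_from_calls(g, fam$phases)
  org_post <- fsmapr:::origins_from_calls(res$geno, fam$phases)
  inf <- informative_markers(g)
  expect_lte(nrow(detect_singletons(org_post, 1:9, inf)),
             nrow(detect_singletons(org_pre, 1:9, inf)))
})

test_that("missing calls are imputed from a unanimous two-sided vote", {
  n_off <- 20
  o <- matrix(rep(c(0L, 1L), each = 10), 8, n_off, byrow = TRUE)
  fam <- testcross_family(asplit(o, 1))
  calls <- fam$geno$calls
  calls[4, 3] <- NA_integer_          # interior missing, origin A side
  g <- fs_geno(calls, fam$geno$seg)
  res <- knn_correct(g, fam$phases, 1:8, seq(0, 35, by = 5))
  expect_equal(res$report$n_imputed, 1L)
  expect_equal(res$geno$calls[4, 3], fam$geno$calls[4, 3])
})

test_that("suspicious markers are flagged and left untouched", {
  set.seed(83)
  n_off <- 40
  o <- matrix(0L, 12, n_off)
  fam <- testcross_family(asplit(o, 1))
  calls <- fam$geno$calls
  # corrupt 40% of one marker's cells
  bad <- sample(n_off, 16)
  calls[6, bad] <- 2L
  g <- fs_geno(calls, fam$geno$seg)
  org <- fsmapr:::origins_from_calls(g, fam$phases)
  inf <- informative_markers(g)
  s <- detect_singletons(org, 1:12, inf)
  susp <- flag_suspicious(s, org, inf, threshold_frac = 0.1)
  expect_equal(as.integer(susp), 6L)
  # knn_correct leaves the suspicious marker alone
  res <- knn_correct(g, fam$phases, 1:12, seq(0, 55, by = 5),
                     suspicious_frac = 0.1)
  expect_equal(res$report$n_flagged_suspicious, 1L)
  expect_identical(res$geno$calls[6, ], g$calls[6, ])
  # no flags on clean counts
  expect_length(flag_suspicious(s[0, ], org, inf), 0L)
})
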