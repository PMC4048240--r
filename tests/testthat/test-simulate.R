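# Simulator: meiosis model, noise injection, blockwise benchmark series,
# depth-dependent calling.

test_that("zero-length chromosome gives non-recombinant meioses", {
  sim <- simulate_family(sim_config(n_offspring = 50, n_markers = 20,
                                    chrom_length_cM = 0, seed = 1))
  for (par in c("maternal", "paternal")) {
    o <- sim$truth$origins[[par]]
    expect_true(all(apply(o, 2, function(v) length(unique(v)) == 1)))
  }
})

test_that("recombinant fractions follow the inverse Haldane function", {
  sim <- simulate_family(sim_config(n_offspring = 10000, n_markers = 2,
                                    chrom_length_cM = 20, seed = 7))
  d <- diff(sim$truth$positions$pos_cM)
  r_exp <- cM_to_r(d)
  for (par in c("maternal", "paternal")) {
    o <- sim$truth$origins[[par]]
    r_obs <- mean(o[1, ] != o[2, ])
    se <- sqrt(r_exp * (1 - r_exp) / 10000)
    expect_lt(abs(r_obs - r_exp), 3 * se)
  }
  # sanity of the closed form itself at the documented value
  expect_equal(cM_to_r(10), 0.0906, tolerance = 1e-3)
})

test_that("crossover counts are consistent with map length (no interference)", {
  sim <- simulate_family(sim_config(n_offspring = 2000, n_markers = 50,
                                    chrom_length_cM = 100, seed = 3))
  pos <- sim$truth$positions$pos_cM
  r_int <- cM_to_r(diff(pos))
  expected <- sum(r_int)             # observable switches per meiosis
  o <- sim$truth$origins$maternal
  obs <- mean(colSums(o[-1, ] != o[-nrow(o), ]))
  se <- sqrt(sum(r_int * (1 - r_int)) / 2000)
  expect_lt(abs(obs - expected), 3 * se)
})

test_that("error and missing injection hit their nominal rates", {
  cfg <- sim_config(n_offspring = 200, n_markers = 200,
                    error_rate = 0.05, missing_rate = 0.1, seed = 11)
  sim <- simulate_family(cfg)
  n <- 200 * 200
  err <- mean(sim$truth$error_mask)
  mis <- mean(sim$truth$missing_mask)
  # error mask survives only where missing did not blank the cell
  expect_lt(abs(err - 0.05 * 0.9), 3 * sqrt(0.045 * 0.955 / n))
  expect_lt(abs(mis - 0.10), 3 * sqrt(0.1 * 0.9 / n))
  expect_true(all(!(sim$truth$error_mask & sim$truth$missing_mask)))
  # error cells differ from truth, missing cells are NA
  expect_true(all(is.na(sim$geno$calls[sim$truth$missing_mask])))
  expect_true(all(sim$geno$calls[sim$truth$error_mask] !=
                    sim$truth$calls$calls[sim$truth$error_mask]))
})

test_that("identical config and seed reproduce bit-identical output", {
  cfg <- sim_config(n_offspring = 60, n_markers = 40, error_rate = 0.1,
                    missing_rate = 0.1, seed = 99)
  s1 <- simulate_family(cfg)
  s2 <- simulate_family(cfg)
  expect_identical(s1$geno$calls, s2$geno$calls)
  expect_identical(s1$truth$positions, s2$truth$positions)
  expect_identical(s1$truth$origins, s2$truth$origins)
})

test_that("simulated class frequencies match the expected ratios", {
  sim <- simulate_family(sim_config(n_offspring = 2000, n_markers = 40,
                                    seed = 5))
  qc <- fsmapr:::segregation_qc(sim$truth$calls)
  # 40 markers: no catastrophic deviation from the Mendelian ratio
  expect_true(all(qc$p > 1e-6))
})

test_that("blockwise series reproduces the aggregate benchmark rates", {
  set.seed(20)
  ds <- blockwise_dataset(7, 100, base_cfg = sim_config(n_offspring = 200,
                                                        seed = 20))
  rates <- default_block_rates()
  expect_length(ds, 7)
  # independent oracle for the per-block rates implied by the aggregates
  agg_e <- rates$error_pct / 100
  agg_m <- rates$missing_pct / 100
  block_e <- diff(c(0, seq_along(agg_e) * agg_e))
  block_m <- diff(c(0, seq_along(agg_m) * agg_m))
  for (b in c(1, 2, 7)) {
    d <- ds[[b]]
    n <- 100 * b * 200
    m_target <- agg_m[b]
    # surviving error mask: per-block error thinned by that block's
    # missing rate (high-error blocks are also high-missing, so the
    # dataset-level expectation is the per-block average, not A_e(1-A_m))
    e_eff <- mean(block_e[1:b] * (1 - block_m[1:b]))
    e_obs <- mean(d$truth$error_mask)
    m_obs <- mean(d$truth$missing_mask)
    expect_lt(abs(e_obs - e_eff),
              3 * sqrt(max(e_eff * (1 - e_eff), 1e-6) / n) + 1e-9)
    expect_lt(abs(m_obs - m_target),
              3 * sqrt(max(m_target * (1 - m_target), 1e-6) / n) + 1e-9)
  }
  # first block is clean and complete
  expect_equal(sum(ds[[1]]$truth$error_mask), 0)
  expect_equal(sum(ds[[1]]$truth$missing_mask), 0)
  # cumulative nesting: shared markers carry identical observed calls
  shared <- intersect(ds[[2]]$geno$marker_ids, ds[[7]]$geno$marker_ids)
  expect_setequal(shared, ds[[2]]$geno$marker_ids)
  expect_identical(ds[[2]]$geno$calls[shared, ],
                   ds[[7]]$geno$calls[shared, ])
})

test_that("depth calling matches exact enumeration oracles", {
  # large depth: both alleles of a heterozygote are always seen
  r <- simulate_depth_calling("abxcd", depth = 60, n_loci = 2000,
                              seed = 2)
  expect_lt(r[["error_rate"]], 0.01)
  expect_lt(r[["missing_rate"]], 0.01)

  # depth 1, strict abstention at nnxnp: oracle by enumeration
  # nn (p=1/2) reads n -> {nn, np} ambiguous -> missing
  # np (p=1/2) reads n (1/2) -> ambiguous -> missing; reads p -> np
  r <- simulate_depth_calling("nnxnp", depth = 1, n_loci = 20000,
                              partial = "missing", seed = 3)
  expect_equal(r[["error_rate"]], 0)
  se <- sqrt(0.75 * 0.25 / 20000)
  expect_lt(abs(r[["missing_rate"]] - 0.75), 4 * se)

  # depth 1, uniform guessing at nnxnp: oracle error
  # nn: guess in {nn, np} -> wrong w.p. 1/2; np read n: wrong w.p. 1/2
  # total error = 1/2 * 1/2 + 1/2 * 1/2 * 1/2 = 0.375
  r <- simulate_depth_calling("nnxnp", depth = 1, n_loci = 20000,
                              partial = "guess", seed = 4)
  expect_equal(r[["missing_rate"]], 0)
  se <- sqrt(0.375 * 0.625 / 20000)
  expect_lt(abs(r[["error_rate"]] - 0.375), 4 * se)

  # depth 2, abxcd (always heterozygous), homozygote rule: a het call
  # needs both alleles; single-allele patterns have no valid homozygote
  # -> missing w.p. 1/2 (both reads same allele), never an error
  r <- simulate_depth_calling("abxcd", depth = 2, n_loci = 20000,
                              partial = "homozygote", seed = 5)
  expect_equal(r[["error_rate"]], 0)
  se <- sqrt(0.5 * 0.5 / 20000)
  expect_lt(abs(r[["missing_rate"]] - 0.5), 4 * se)

  # depth 2, hkxhk with homozygote rule: oracle by enumeration
  # hh: reads hh -> called hh (correct).  kk likewise.
  # hk (p=1/2): reads {hh:1/4 -> hh wrong, kk:1/4 -> kk wrong, mixed:1/2
  # -> hk correct}.  error = 1/2 * 1/2 = 1/4, missing = 0
  r <- simulate_depth_calling("hkxhk", depth = 2, n_loci = 20000,
                              partial = "homozygote", seed = 6)
  expect_equal(r[["missing_rate"]], 0)
  se <- sqrt(0.25 * 0.75 / 20000)
  expect_lt(abs(r[["error_rate"]] - 0.25), 4 * se)
})
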