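# Full-sib family simulator with known truth.
#
# Emulates genotype data of a single outbred CP family: markers placed
# uniformly at random along chromosomes, meioses without crossover
# interference (Haldane model), and independent error / missing injection
# at configured cell-level rates.

#' Simulation configuration
#'
#' @param n_offspring family size.
#' @param n_markers total marker count.
#' @param n_chromosomes number of chromosomes (= linkage groups).
#' @param chrom_length_cM chromosome length(s) in cM; recycled.
#' @param seg_type_mix named proportions over the five segregation codes.
#' @param error_rate cell-level probability that a call is replaced by a
#'   uniformly chosen different valid class.
#' @param missing_rate cell-level probability that a call is blanked
#'   (applied after error injection; a blanked cell loses its error).
#' @param seed integer seed; the generator is fully reproducible from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_offspring = 200, n_markers = 200,
                       n_chromosomes = 1, chrom_length_cM = 100,
                       seg_type_mix = c(abxcd = 0.10, efxeg = 0.15,
                                        hkxhk = 0.25, nnxnp = 0.25,
                                        lmxll = 0.25),
                       error_rate = 0, missing_rate = 0, seed = 1L) {
  stopifnot(n_offspring >= 1, n_markers >= 1, n_chromosomes >= 1,
            all(chrom_length_cM >= 0),
            error_rate >= 0, error_rate <= 1,
            missing_rate >= 0, missing_rate <= 1)
  seg_type_mix <- seg_type_mix / sum(seg_type_mix)
  if (!all(names(seg_type_mix) %in% SEG_CODES))
    stop("seg_type_mix names must be segregation codes", call. = FALSE)
  chrom_length_cM <- rep_len(chrom_length_cM, n_chromosomes)
  structure(list(n_offspring = as.integer(n_offspring),
                 n_markers = as.integer(n_markers),
                 n_chromosomes = as.integer(n_chromosomes),
                 chrom_length_cM = chrom_length_cM,
                 seg_type_mix = seg_type_mix,
                 error_rate = error_rate, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a full-sib family with known truth
#'
#' Markers are placed uniformly at random along each chromosome and sorted;
#' each offspring inherits, for each parental meiosis, a chromatid sequence
#' in which switches between adjacent markers occur independently with
#' probability given by the inverse Haldane function of the interval
#' distance (no interference).  Observed calls are the true genotype
#' classes with errors substituted uniformly among the other valid classes
#' and missing cells blanked, both i.i.d. across cells.
#'
#' @param cfg a [sim_config()].
#' @return list with elements
#'   `geno` (observed [fs_geno()]),
#'   `truth`: list with `positions` (data.frame marker, chrom, pos_cM),
#'   `phases` (marker x 2 matrix, 0/1/NA), `origins`
#'   (list maternal/paternal marker x offspring 0/1 matrices),
#'   `calls` (true fs_geno), `error_mask`, `missing_mask`
#'   (marker x offspring logicals).
#' @export
simulate_family <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n_off <- cfg$n_offspring
  n_mrk <- cfg$n_markers

  # marker placement: chromosome sizes proportional to length (at least 1)
  chrom <- sort(sample.int(cfg$n_chromosomes, n_mrk, replace = TRUE,
                           prob = (cfg$chrom_length_cM + 1e-9)))
  pos <- numeric(n_mrk)
  for (c in seq_len(cfg$n_chromosomes)) {
    idx <- which(chrom == c)
    pos[idx] <- sort(stats::runif(length(idx), 0, cfg$chrom_length_cM[c]))
  }
  marker_ids <- sprintf("M%04d", seq_len(n_mrk))

  seg <- sample(names(cfg$seg_type_mix), n_mrk, replace = TRUE,
                prob = cfg$seg_type_mix)
  inf <- t(vapply(seg, function(s) seg_type(s)$informative, logical(2)))
  phases <- matrix(NA_integer_, n_mrk, 2,
                   dimnames = list(marker_ids, c("maternal", "paternal")))
  phases[, 1][inf[, 1]] <- sample(0:1, sum(inf[, 1]), replace = TRUE)
  phases[, 2][inf[, 2]] <- sample(0:1, sum(inf[, 2]), replace = TRUE)

  # meioses: chromatid-origin chains per parent (all markers, both parents,
  # regardless of informativeness -- truth exists everywhere)
  sim_chain <- function() {
    o <- matrix(0L, n_mrk, n_off)
    for (c in seq_len(cfg$n_chromosomes)) {
      idx <- which(chrom == c)
      if (!length(idx)) next
      o[idx[1], ] <- sample(0:1, n_off, replace = TRUE)
      if (length(idx) > 1) {
        r <- cM_to_r(diff(pos[idx]))
        for (j in seq_along(r)) {
          sw <- stats::runif(n_off) < r[j]
          o[idx[j + 1], ] <- ifelse(sw, 1L - o[idx[j], ], o[idx[j], ])
        }
      }
    }
    o
  }
  orig_m <- sim_chain()
  orig_p <- sim_chain()
  dimnames(orig_m) <- dimnames(orig_p) <- list(marker_ids, NULL)

  # true genotype classes
  calls <- matrix(NA_integer_, n_mrk, n_off,
                  dimnames = list(marker_ids, NULL))
  for (i in seq_len(n_mrk)) {
    st <- seg_type(seg[i])
    # class lookup for the 4 chromatid combinations under this phase
    lut <- matrix(NA_integer_, 2, 2)
    for (a in 0:1) for (b in 0:1)
      lut[a + 1, b + 1] <- class_from_origins(
        a, b, seg[i],
        if (is.na(phases[i, 1])) 0L else phases[i, 1],
        if (is.na(phases[i, 2])) 0L else phases[i, 2])
    calls[i, ] <- lut[cbind(orig_m[i, ] + 1L, orig_p[i, ] + 1L)]
  }
  true_geno <- fs_geno(calls, seg, marker_ids)

  inj <- inject_noise(true_geno, cfg$error_rate, cfg$missing_rate)

  list(geno = inj$geno,
       truth = list(
         positions = data.frame(marker = marker_ids, chrom = chrom,
                                pos_cM = pos, stringsAsFactors = FALSE),
         phases = phases,
         origins = list(maternal = orig_m, paternal = orig_p),
         calls = true_geno,
         error_mask = inj$error_mask,
         missing_mask = inj$missing_mask))
}

# Inject i.i.d. errors (uniform among other valid classes) then missing.
# Uses the current RNG stream.
inject_noise <- function(true_geno, error_rate, missing_rate) {
  calls <- true_geno$calls
  n_mrk <- nrow(calls); n_off <- ncol(calls)
  err <- matrix(stats::runif(n_mrk * n_off) < error_rate, n_mrk, n_off)
  err[is.na(calls)] <- FALSE
  if (any(err)) {
    nclass <- vapply(true_geno$seg,
                     function(s) length(seg_type(s)$classes), integer(1))
    idx <- which(err, arr.ind = TRUE)
    k <- nclass[idx[, 1]]
    # uniform among the other k-1 classes
    shift <- floor(stats::runif(nrow(idx)) * (k - 1)) + 1
    calls[err] <- as.integer((calls[err] - 1L + shift) %% k + 1L)
  }
  mis <- matrix(stats::runif(n_mrk * n_off) < missing_rate, n_mrk, n_off)
  calls[mis] <- NA_integer_
  err[mis] <- FALSE               # a blanked cell loses its injected error
  dimnames(err) <- dimnames(mis) <- dimnames(calls)
  list(geno = fs_geno(calls, true_geno$seg, true_geno$marker_ids),
       error_mask = err, missing_mask = mis)
}

#' Default aggregate error/missing rates for the incremental benchmark
#'
#' Aggregate dataset-level rates (in percent) for the cumulative
#' 100..1000-marker benchmark series, used as inputs by
#' [blockwise_dataset()].
#'
#' @return data.frame with `n_markers`, `error_pct`, `missing_pct`.
#' @export
default_block_rates <- function() {
  data.frame(
    n_markers = seq(100, 1000, by = 100),
    error_pct = c(0, 2.37, 4.61, 6.69, 6.32, 8.40, 10.25, 11.90, 13.20,
                  14.35),
    missing_pct = c(0, 2.50, 5.00, 7.50, 7.00, 10.00, 12.86, 15.63, 18.33,
                    21.00))
}

#' Incremental benchmark datasets with rising error and missingness
#'
#' Builds a series of cumulative datasets of `block_size`, `2*block_size`,
#' ..., `n_blocks*block_size` markers from one simulated family.  Marker
#' blocks are appended one at a time; each block carries its own error and
#' missing rate, chosen so that the aggregate rate of the cumulative
#' dataset with `b` blocks matches `error_pct[b]` / `missing_pct[b]` in
#' expectation.
#'
#' @param n_blocks number of blocks to append.
#' @param block_size markers per block (default 100).
#' @param rates data.frame as returned by [default_block_rates()]
#'   (aggregate percentages per cumulative dataset); defaults to the
#'   built-in benchmark series.
#' @param base_cfg [sim_config()] supplying family size, chromosome layout
#'   and segregation mix; its `n_markers`, `error_rate`, `missing_rate` are
#'   overridden.
#' @return list of `n_blocks` simulation results (as [simulate_family()]),
#'   the b-th containing the first `b` blocks.
#' @export
blockwise_dataset <- function(n_blocks, block_size = 100,
                              rates = default_block_rates(),
                              base_cfg = sim_config()) {
  stopifnot(n_blocks >= 1, n_blocks <= nrow(rates))
  agg_e <- rates$error_pct[seq_len(n_blocks)] / 100
  agg_m <- rates$missing_pct[seq_len(n_blocks)] / 100
  b <- seq_len(n_blocks)
  # per-block rate from cumulative aggregates: B_b = b*A_b - (b-1)*A_{b-1}
  block_e <- diff(c(0, b * agg_e))
  block_m <- diff(c(0, b * agg_m))
  if (any(block_e < -1e-9 | block_e > 1 | block_m < -1e-9 | block_m > 1))
    stop("aggregate rates imply per-block rates outside [0, 1]",
         call. = FALSE)
  block_e <- pmax(block_e, 0); block_m <- pmax(block_m, 0)

  cfg <- base_cfg
  cfg$n_markers <- as.integer(n_blocks * block_size)
  cfg$error_rate <- 0; cfg$missing_rate <- 0
  base <- simulate_family(cfg)

  # assign markers to blocks at random (block membership is independent of
  # genome position), then inject per-block noise once
  block_of <- sample(rep(seq_len(n_blocks), each = block_size))
  calls <- base$truth$calls$calls
  err_mask <- mis_mask <- matrix(FALSE, nrow(calls), ncol(calls),
                                 dimnames = dimnames(calls))
  noisy <- calls
  for (blk in seq_len(n_blocks)) {
    rows <- which(block_of == blk)
    sub <- subset_markers(base$truth$calls, rows)
    inj <- inject_noise(sub, block_e[blk], block_m[blk])
    noisy[rows, ] <- inj$geno$calls
    err_mask[rows, ] <- inj$error_mask
    mis_mask[rows, ] <- inj$missing_mask
  }

  out <- vector("list", n_blocks)
  for (bb in seq_len(n_blocks)) {
    rows <- which(block_of <= bb)
    truth <- base$truth
    truth$positions <- truth$positions[rows, , drop = FALSE]
    truth$phases <- truth$phases[rows, , drop = FALSE]
    truth$origins <- lapply(truth$origins,
                            function(m) m[rows, , drop = FALSE])
    truth$calls <- subset_markers(truth$calls, rows)
    truth$error_mask <- err_mask[rows, , drop = FALSE]
    truth$missing_mask <- mis_mask[rows, , drop = FALSE]
    out[[bb]] <- list(
      geno = fs_geno(noisy[rows, , drop = FALSE],
                     base$truth$calls$seg[rows],
                     base$truth$calls$marker_ids[rows]),
      truth = truth)
  }
  out
}

#' Depth-dependent genotype-calling error and missing rates
#'
#' Emulates naive genotype calling from shallow sequencing: for each locus
#' a true genotype class is drawn from the Mendelian ratio, `depth` reads
#' each sample one of the genotype's two allele copies uniformly, and the
#' configured calling rule converts the observed allele multiset into a
#' call.
#'
#' @param code segregation code.
#' @param depth reads per locus (>= 1).
#' @param n_loci number of simulated loci.
#' @param partial behaviour when the observed alleles do not uniquely
#'   identify a class: `"homozygote"` calls the single-allele homozygote
#'   class when it is valid (else missing), `"missing"` always abstains,
#'   `"guess"` picks uniformly among compatible classes.
#' @param seed integer seed.
#' @return named numeric vector `c(error_rate, missing_rate)` (realized
#'   fractions of miscalled and uncalled loci).
#' @export
simulate_depth_calling <- function(code, depth, n_loci = 10000,
                                   partial = c("homozygote", "missing",
                                               "guess"),
                                   seed = 1L) {
  stopifnot(depth >= 1, n_loci >= 1)
  partial <- match.arg(partial)
  set.seed(seed)
  st <- seg_type(code)
  allele_pairs <- lapply(st$classes, function(cl)
    strsplit(cl, "")[[1]])
  true_cl <- sample.int(length(st$classes), n_loci, replace = TRUE,
                        prob = st$ratio)
  called <- integer(n_loci)    # 0 = missing
  err <- 0L
  for (i in seq_len(n_loci)) {
    al <- allele_pairs[[true_cl[i]]]
    reads <- al[sample.int(2, depth, replace = TRUE)]
    seen <- sort(unique(reads))
    if (length(seen) == 2) {
      lab <- paste0(seen, collapse = "")
      called[i] <- match(lab, st$classes)
    } else {
      compat <- which(vapply(allele_pairs,
                             function(p) seen %in% p, logical(1)))
      if (length(compat) == 1L) {
        called[i] <- compat
      } else if (partial == "homozygote") {
        hom <- match(paste0(seen, seen), st$classes)
        called[i] <- if (is.na(hom)) 0L else hom
      } else if (partial == "guess") {
        called[i] <- compat[sample.int(length(compat), 1)]
      }                               # "missing": leave 0
    }
  }
  miss <- called == 0L
  err <- sum(!miss & called != true_cl)
  c(error_rate = err / n_loci, missing_rate = mean(miss))
}
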