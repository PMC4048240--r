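# Map-quality metrics and exports: singleton rate, order correlation,
# map length, heat-map and haplotype-map matrices, truth-based scoring.

#' Singleton rate of an ordered data set
#'
#' Singleton count divided by the number of determinable-origin cells
#' (ambiguous and missing cells cannot host singletons and are excluded
#' from the denominator).
#'
#' @param origins origin matrices (list maternal/paternal).
#' @param order marker indices in map order.
#' @param inf informativeness matrix.
#' @return fraction in `[0, 1]`.
#' @export
singleton_rate <- function(origins, order, inf) {
  sing <- detect_singletons(origins, order, inf)
  denom <- 0L
  for (par in c("maternal", "paternal")) {
    sub <- order[inf[order, par]]
    denom <- denom + sum(!is.na(origins[[par]][sub, , drop = FALSE]))
  }
  if (denom == 0L) return(0)
  nrow(sing) / denom
}

#' Orientation-free order correlation
#'
#' Absolute Spearman rank correlation between an estimated marker order
#' and reference positions; taking the absolute value makes the metric
#' invariant to map orientation.
#'
#' @param est_order marker ids (or indices) in estimated order.
#' @param ref_positions named numeric vector of reference positions (names
#'   = marker ids), or unnamed vector parallel to the marker universe.
#' @return `|Spearman rho|` over the shared markers.
#' @export
order_correlation <- function(est_order, ref_positions) {
  if (!is.null(names(ref_positions))) {
    shared <- intersect(as.character(est_order), names(ref_positions))
    if (length(shared) < 3)
      stop("need at least 3 shared markers", call. = FALSE)
    est_rank <- match(shared, as.character(est_order))
    ref <- ref_positions[shared]
  } else {
    est_rank <- seq_along(est_order)
    ref <- ref_positions[est_order]
    if (length(ref) < 3) stop("need at least 3 shared markers",
                              call. = FALSE)
  }
  abs(stats::cor(est_rank, ref, method = "spearman"))
}

#' Map length in cM
#'
#' @param map result of [build_group_map()] (or any list with `pos_cM`,
#'   `maternal$pos_cM`, `paternal$pos_cM`).
#' @return named numeric: `integrated`, `maternal`, `paternal` lengths.
#' @export
map_length <- function(map) {
  safe_max <- function(x) if (length(x)) max(x) else 0
  c(integrated = safe_max(map$pos_cM),
    maternal = safe_max(map$maternal$pos_cM),
    paternal = safe_max(map$paternal$pos_cM))
}

#' Heat-map matrix in map order
#'
#' Reorders a pairwise recombination (or LOD) matrix by the map order; a
#' correct map shows a monotone band of small r near the diagonal.
#'
#' @param order marker indices in map order.
#' @param pairwise symmetric marker x marker matrix.
#' @param path optional TSV output path.
#' @return the reordered matrix (invisibly when written).
#' @export
export_heatmap <- function(order, pairwise, path = NULL) {
  m <- pairwise[order, order, drop = FALSE]
  if (!is.null(path)) {
    utils::write.table(format(m, digits = 6), path, sep = "\t",
                       quote = FALSE, col.names = NA)
    return(invisible(m))
  }
  m
}

#' Haplotype (graphical genotype) map export
#'
#' Rows are markers in map order; each offspring contributes two columns
#' (maternal, paternal meiosis) of chromatid-origin codes `A`, `B` or `-`
#' (undeterminable).  Crossovers appear as block boundaries.
#'
#' @param origins origin matrices.
#' @param order marker indices in map order.
#' @param marker_ids marker identifiers.
#' @param path optional TSV output path.
#' @return character matrix of origin codes (invisibly when written).
#' @export
export_haplotype_map <- function(origins, order, marker_ids,
                                 path = NULL) {
  code <- function(x) ifelse(is.na(x), "-", ifelse(x == 0L, "A", "B"))
  n_off <- ncol(origins$maternal)
  m <- matrix("", length(order), 2L * n_off)
  m[, seq(1, 2 * n_off, by = 2)] <- code(origins$maternal[order, ])
  m[, seq(2, 2 * n_off, by = 2)] <- code(origins$paternal[order, ])
  rownames(m) <- marker_ids[order]
  colnames(m) <- paste0("off", rep(seq_len(n_off), each = 2),
                        c("_m", "_p"))
  if (!is.null(path)) {
    utils::write.table(m, path, sep = "\t", quote = FALSE,
                       col.names = NA)
    return(invisible(m))
  }
  m
}

#' Score a corrected data set against simulator truth
#'
#' Compares the final (corrected/imputed) genotype matrix with the
#' simulator's true calls and injection masks and reports the benchmark
#' quantities: detection and accuracy of error correction and missing
#' imputation, plus residual error and missing rates.
#'
#' @param final_geno corrected [fs_geno()].
#' @param observed_geno the observed (noisy) input [fs_geno()].
#' @param truth the `truth` element of a [simulate_family()] result (needs
#'   `calls`, `error_mask`, `missing_mask`); marker sets must match.
#' @return named numeric vector (all percentages except counts):
#'   `error_detected_pct` (injected errors whose value was altered),
#'   `error_accuracy_pct` (share of re-assigned error cells restored to
#'   the true class), `residual_error_pct` (cells called but wrong, of all
#'   cells), `missing_detected_pct` (injected missings given a call),
#'   `imputation_accuracy_pct` (share of imputed cells equal to truth),
#'   `residual_missing_pct` (cells without a call, of all cells).
#' @export
score_against_truth <- function(final_geno, observed_geno, truth) {
  stopifnot(identical(final_geno$marker_ids, truth$calls$marker_ids))
  fin <- final_geno$calls
  obs <- observed_geno$calls
  tru <- truth$calls$calls
  err <- truth$error_mask & !truth$missing_mask
  mis <- truth$missing_mask
  n_cells <- length(tru)

  changed <- err & (is.na(fin) | fin != obs)
  reassigned <- err & !is.na(fin) & fin != obs
  acc <- if (any(reassigned)) mean(fin[reassigned] == tru[reassigned])
         else NA_real_
  imputed <- mis & !is.na(fin)
  imp_acc <- if (any(imputed)) mean(fin[imputed] == tru[imputed])
             else NA_real_
  c(error_detected_pct = 100 * if (any(err)) mean(changed[err]) else 0,
    error_accuracy_pct = 100 * acc,
    residual_error_pct = 100 * sum(!is.na(fin) & fin != tru) / n_cells,
    missing_detected_pct = 100 * if (any(mis)) mean(imputed[mis]) else 0,
    imputation_accuracy_pct = 100 * imp_acc,
    residual_missing_pct = 100 * mean(is.na(fin)))
}
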