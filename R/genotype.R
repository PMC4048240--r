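# Genotype-matrix container: the pipeline's main input.

#' Construct a CP genotype matrix
#'
#' Bundles per-marker genotype-class calls for a single outbred full-sib
#' family.  Calls are stored as integer indices into each marker's
#' segregation-type class list ([seg_type()]); `NA` encodes a missing call.
#'
#' @param calls integer matrix, markers x offspring; entries are class
#'   indices or `NA`.
#' @param seg character vector of segregation codes, one per marker.
#' @param marker_ids optional marker identifiers (default: rownames of
#'   `calls` or `M1..Mn`).
#' @return an object of class `fs_geno` with elements `calls`, `seg`,
#'   `marker_ids`, `n_off`.
#' @export
fs_geno <- function(calls, seg, marker_ids = NULL) {
  if (!is.matrix(calls)) stop("calls must be a matrix", call. = FALSE)
  storage.mode(calls) <- "integer"
  n_mrk <- nrow(calls)
  if (length(seg) != n_mrk)
    stop("length(seg) != nrow(calls)", call. = FALSE)
  seg <- tolower(as.character(seg))
  bad <- setdiff(unique(seg), SEG_CODES)
  if (length(bad))
    stop("unknown segregation code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (is.null(marker_ids)) {
    marker_ids <- rownames(calls)
    if (is.null(marker_ids)) marker_ids <- paste0("M", seq_len(n_mrk))
  }
  if (anyDuplicated(marker_ids))
    stop("duplicated marker ids", call. = FALSE)
  rownames(calls) <- marker_ids
  # validate class indices
  for (code in unique(seg)) {
    k <- length(seg_type(code)$classes)
    rows <- which(seg == code)
    v <- calls[rows, , drop = FALSE]
    bad <- which(!is.na(v) & (v < 1L | v > k), arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("invalid class index at marker %s, offspring %d (%s)",
                   marker_ids[rows[bad[1, 1]]], bad[1, 2], code),
           call. = FALSE)
  }
  structure(list(calls = calls, seg = seg, marker_ids = marker_ids,
                 n_off = ncol(calls)),
            class = "fs_geno")
}

#' @export
print.fs_geno <- function(x, ...) {
  cat(sprintf("CP genotype matrix: %d markers x %d offspring\n",
              nrow(x$calls), x$n_off))
  tab <- table(factor(x$seg, levels = SEG_CODES))
  cat("  segregation types:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

# Subset markers (by index or id), keeping all offspring.
subset_markers <- function(geno, idx) {
  if (is.character(idx)) idx <- match(idx, geno$marker_ids)
  fs_geno(geno$calls[idx, , drop = FALSE], geno$seg[idx],
          geno$marker_ids[idx])
}

# Per-marker chi-square QC against the expected Mendelian ratio.
# Returns data.frame(marker, chisq, df, p).
segregation_qc <- function(geno) {
  n_mrk <- nrow(geno$calls)
  out <- data.frame(marker = geno$marker_ids,
                    chisq = NA_real_, df = NA_integer_, p = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n_mrk)) {
    st <- seg_type(geno$seg[i])
    k <- length(st$classes)
    obs <- tabulate(geno$calls[i, ], nbins = k)
    n <- sum(obs)
    if (n == 0) next
    e <- st$ratio * n
    out$chisq[i] <- sum((obs - e)^2 / e)
    out$df[i] <- k - 1L
    out$p[i] <- stats::pchisq(out$chisq[i], k - 1L, lower.tail = FALSE)
  }
  out
}
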