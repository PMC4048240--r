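# File formats: CP genotype tables (loc dialect and plain TSV), map and
# report exports, run manifest.

#' Read a CP genotype table
#'
#' Auto-detects two dialects.  The loc dialect has header lines
#' `popt = CP`, `nloc = <n>`, `nind = <n>` followed by one record per
#' marker: `id <segcode> call call ...` with calls written as genotype
#' class labels (e.g. `ac`, `hk`, `np`) and `--` for missing.  The TSV
#' dialect has a header row `marker seg off1 ... offN` with the same call
#' labels.
#'
#' @param path input file.
#' @param qc_warn emit a warning listing markers whose class frequencies
#'   fail a chi-square test against the expected segregation ratio at
#'   p < 1e-4 (default TRUE).
#' @return an [fs_geno()] object.
#' @export
read_genotypes <- function(path, qc_warn = TRUE) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(;|#|$)", lines)]
  if (!length(lines)) stop("empty genotype file: ", path, call. = FALSE)
  is_tsv <- grepl("^marker\\b", lines[1], ignore.case = TRUE)
  if (is_tsv) {
    toks <- strsplit(lines[-1], "\t")
    n_ind <- length(strsplit(lines[1], "\t")[[1]]) - 2L
    recs <- lapply(seq_along(toks), function(i) {
      t <- toks[[i]]
      if (length(t) != n_ind + 2L)
        stop(sprintf("malformed record at line %d of %s", i + 1L, path),
             call. = FALSE)
      t
    })
    parse_records(recs, n_ind, path)
  } else {
    hdr <- grep("=", lines, value = TRUE)
    kv <- function(key) {
      h <- grep(paste0("^\\s*", key, "\\s*="), hdr, value = TRUE)
      if (!length(h)) return(NA_character_)
      trimws(sub(".*=", "", h[1]))
    }
    popt <- kv("popt")
    if (!is.na(popt) && toupper(popt) != "CP")
      stop("unsupported population type: ", popt, call. = FALSE)
    n_ind <- as.integer(kv("nind"))
    body <- lines[!grepl("=", lines)]
    toks <- strsplit(trimws(body), "\\s+")
    if (is.na(n_ind)) n_ind <- length(toks[[1]]) - 2L
    recs <- lapply(seq_along(toks), function(i) {
      t <- toks[[i]]
      if (length(t) != n_ind + 2L)
        stop(sprintf("malformed record at line %d of %s (expected %d calls)",
                     which(lines == body[i])[1], path, n_ind),
             call. = FALSE)
      t
    })
    parse_records(recs, n_ind, path, qc_warn = qc_warn)
  }
}

parse_records <- function(recs, n_ind, path, qc_warn = TRUE) {
  n_mrk <- length(recs)
  ids <- vapply(recs, `[`, character(1), 1)
  seg <- gsub("[<>]", "", vapply(recs, `[`, character(1), 2))
  bad <- which(!tolower(seg) %in% SEG_CODES)
  if (length(bad))
    stop("unknown segregation code '", seg[bad[1]], "' for marker ",
         ids[bad[1]], call. = FALSE)
  seg <- tolower(seg)
  calls <- matrix(NA_integer_, n_mrk, n_ind)
  for (i in seq_len(n_mrk)) {
    cl <- seg_type(seg[i])$classes
    lab <- recs[[i]][-(1:2)]
    v <- match(lab, cl)
    v[lab == MISSING_CODE] <- NA_integer_
    unknown <- which(is.na(v) & lab != MISSING_CODE)
    if (length(unknown))
      stop("invalid call '", lab[unknown[1]], "' for marker ", ids[i],
           " (", seg[i], ")", call. = FALSE)
    calls[i, ] <- v
  }
  geno <- fs_geno(calls, seg, ids)
  if (qc_warn) {
    qc <- segregation_qc(geno)
    distorted <- qc$marker[!is.na(qc$p) & qc$p < 1e-4]
    if (length(distorted))
      warning("segregation distortion (p < 1e-4) at ",
              length(distorted), " marker(s): ",
              paste(utils::head(distorted, 5), collapse = ", "),
              if (length(distorted) > 5) ", ..." else "",
              call. = FALSE)
  }
  geno
}

#' Write a CP genotype table
#'
#' @param geno an [fs_geno()] object.
#' @param path output file.
#' @param format `"loc"` (default) or `"tsv"` (see [read_genotypes()]).
#' @export
write_genotypes <- function(geno, path, format = c("loc", "tsv")) {
  format <- match.arg(format)
  labels <- function(i) {
    cl <- seg_type(geno$seg[i])$classes
    v <- cl[geno$calls[i, ]]
    v[is.na(v)] <- MISSING_CODE
    v
  }
  if (format == "loc") {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(c("; CP genotype table",
                 "popt = CP",
                 paste0("nloc = ", nrow(geno$calls)),
                 paste0("nind = ", geno$n_off)), con)
    for (i in seq_len(nrow(geno$calls)))
      writeLines(paste(c(geno$marker_ids[i],
                         paste0("<", geno$seg[i], ">"), labels(i)),
                       collapse = " "), con)
  } else {
    m <- t(vapply(seq_len(nrow(geno$calls)), labels,
                  character(geno$n_off)))
    df <- data.frame(marker = geno$marker_ids, seg = geno$seg, m,
                     stringsAsFactors = FALSE)
    names(df) <- c("marker", "seg", paste0("off", seq_len(geno$n_off)))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Write the simulator truth sidecar
#'
#' @param sim a [simulate_family()] result.
#' @param dir output directory.
#' @return paths written (invisibly).
#' @export
write_sim_truth <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tr <- sim$truth
  side <- cbind(tr$positions,
                phase_m = tr$phases[, 1], phase_p = tr$phases[, 2])
  p1 <- file.path(dir, "truth_markers.tsv")
  utils::write.table(side, p1, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sparse_mask <- function(mask) {
    w <- which(mask, arr.ind = TRUE)
    data.frame(marker = rownames(mask)[w[, 1]], offspring = w[, 2])
  }
  p2 <- file.path(dir, "truth_error_mask.tsv")
  utils::write.table(sparse_mask(tr$error_mask), p2, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  p3 <- file.path(dir, "truth_missing_mask.tsv")
  utils::write.table(sparse_mask(tr$missing_mask), p3, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2, p3))
}

#' Write pipeline outputs
#'
#' Writes, with deterministic file names and byte-stable content: one map
#' TSV per linkage group (marker, integrated and parental cM positions,
#' segregation type, phases), a correction-report TSV, and a JSON run
#' manifest echoing the configuration and seed.
#'
#' @param result an `fs_pipeline_result` from [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @return character vector of written paths (invisibly).
#' @export
write_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (gi in seq_along(result$groups)) {
    g <- result$groups[[gi]]
    pos_m <- rep(NA_real_, length(g$ids))
    pos_m[g$maternal$markers] <- g$maternal$pos_cM
    pos_p <- rep(NA_real_, length(g$ids))
    pos_p[g$paternal$markers] <- g$paternal$pos_cM
    df <- data.frame(
      group = gi,
      marker = g$order_ids,
      position_cM_integrated = sprintf("%.4f", g$pos_cM),
      position_cM_maternal = ifelse(is.na(pos_m[g$order]), "NA",
                                    sprintf("%.4f", pos_m[g$order])),
      position_cM_paternal = ifelse(is.na(pos_p[g$order]), "NA",
                                    sprintf("%.4f", pos_p[g$order])),
      seg_type = g$geno$seg[g$order],
      phase_m = g$phases[g$order, 1],
      phase_p = g$phases[g$order, 2],
      stringsAsFactors = FALSE)
    p <- file.path(out_dir, sprintf("map_group%02d.tsv", gi))
    utils::write.table(df, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
    chg <- do.call(rbind, lapply(seq_along(g$reports), function(r)
      cbind(round = r, g$reports[[r]]$changes)))
    p <- file.path(out_dir, sprintf("corrections_group%02d.tsv", gi))
    utils::write.table(chg, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
  }
  manifest <- list(
    package = "fsmapr",
    version = as.character(utils::packageVersion("fsmapr")),
    seed = result$config$seed,
    config = unclass(result$config)[
      setdiff(names(result$config), "ordering")],
    ordering = unclass(result$config$ordering)[
      setdiff(names(result$config$ordering), "schedule")],
    schedule = unclass(result$config$ordering$schedule),
    n_groups = length(result$groups),
    threshold = result$grouping$threshold)
  p <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, p, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(c(paths, p))
}
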