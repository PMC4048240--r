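# Singleton detection, kNN error correction and missing imputation.
#
# A singleton is a locus in one offspring whose parental origin differs
# from both its nearest determinable neighbours along the map -- the
# fingerprint of a genotyping error on a dense map.

#' Detect singletons
#'
#' Scans, for every offspring and each parental meiosis, the sub-sequence
#' of determinable chromatid origins in map order and flags positions
#' whose origin differs from both nearest determinable neighbours.
#' Terminal loci (a single neighbour) are never singletons.
#'
#' @param origins list of maternal/paternal origin matrices (markers x
#'   offspring, 0/1/NA) as from `origins_from_calls`.
#' @param order marker indices in map order.
#' @param inf marker x 2 logical informativeness matrix.
#' @return data.frame with `marker` (index), `offspring`, `parent`,
#'   `observed`, `neighbor` (the origin of both flanking neighbours).
#' @export
detect_singletons <- function(origins, order, inf) {
  res <- list()
  for (par in c("maternal", "paternal")) {
    sub <- order[inf[order, par]]
    if (length(sub) < 3L) next
    O <- origins[[par]][sub, , drop = FALSE]
    for (o in seq_len(ncol(O))) {
      v <- O[, o]
      idx <- which(!is.na(v))
      if (length(idx) < 3L) next
      vv <- v[idx]
      k <- 2:(length(idx) - 1L)
      s <- k[vv[k] != vv[k - 1L] & vv[k] != vv[k + 1L]]
      if (length(s))
        res[[length(res) + 1L]] <- data.frame(
          marker = sub[idx[s]], offspring = o, parent = par,
          observed = vv[s], neighbor = 1L - vv[s],
          stringsAsFactors = FALSE)
    }
  }
  if (!length(res))
    return(data.frame(marker = integer(0), offspring = integer(0),
                      parent = character(0), observed = integer(0),
                      neighbor = integer(0), stringsAsFactors = FALSE))
  do.call(rbind, res)
}

#' Flag suspicious markers
#'
#' Markers whose singleton count, relative to their determinable
#' informative meioses, exceeds `threshold_frac` are labelled suspicious;
#' such markers are excluded from correction and imputation.
#'
#' @param singletons data.frame from [detect_singletons()].
#' @param origins origin matrices (for the denominator).
#' @param inf informativeness matrix.
#' @param threshold_frac flagging threshold (default 0.1).
#' @param adaptive raise the effective threshold to three times the
#'   median per-marker singleton fraction when that is larger (default
#'   TRUE).  On data where genotyping errors are pervasive every marker
#'   carries a background singleton load; a marker is only "suspicious"
#'   when it stands out from that background, otherwise correction would
#'   switch itself off exactly when it is needed most.
#' @return integer vector of suspicious marker indices, with attribute
#'   `singleton_frac` (per-marker fraction, full length) and `threshold`
#'   (the effective threshold used).
#' @export
flag_suspicious <- function(singletons, origins, inf,
                            threshold_frac = 0.1, adaptive = TRUE) {
  n_mrk <- nrow(origins$maternal)
  cnt <- tabulate(singletons$marker, nbins = n_mrk)
  denom <- rowSums(!is.na(origins$maternal)) +
    rowSums(!is.na(origins$paternal))
  frac <- ifelse(denom > 0, cnt / denom, 0)
  thr <- threshold_frac
  if (adaptive) thr <- max(thr, 3 * stats::median(frac))
  structure(which(frac > thr), singleton_frac = frac, threshold = thr)
}

#' kNN correction of singletons and imputation of missing genotypes
#'
#' Singleton cells and missing calls (at non-suspicious markers) are
#' resolved per parental meiosis by a vote of the `k` nearest
#' determinable, non-singleton loci of the same offspring chain (distance
#' in cM along the map): when at least `majority_frac` of the neighbours
#' agree, the voted chromatid origin replaces the cell's origin.  The
#' voted origins of both meioses are projected back to a genotype class
#' honouring the marker's segregation type and phases; singletons whose
#' vote identifies an error but no replacement class are set to missing
#' ("eliminated").
#'
#' @param geno an [fs_geno()] object.
#' @param phases phase matrix from [anchor_phases()].
#' @param order marker indices in map order.
#' @param pos_cM map positions of `order` (same length).
#' @param k neighbours per vote (default 5).
#' @param majority_frac required agreement among voters for singleton
#'   correction (default 0.8).
#' @param impute_majority_frac required agreement for imputing a missing
#'   call (default 1: unanimity).  Imputation writes a call where nothing
#'   was observed, so it demands more confidence than correction, which
#'   is already backed by singleton evidence; unanimity also filters
#'   cells sitting on a crossover, whose origin is genuinely uncertain.
#' @param suspicious_frac threshold for [flag_suspicious()].
#' @return list with `geno` (corrected [fs_geno()]) and `report`: counts
#'   `n_corrected`, `n_imputed`, `n_eliminated`, `n_flagged_suspicious`,
#'   `singleton_count` (pre-correction), per-marker `singleton_frac`,
#'   `suspicious` (marker ids), and `changes` (audit log: offspring,
#'   marker, old, new, reason).
#' @export
knn_correct <- function(geno, phases, order, pos_cM, k = 5,
                        majority_frac = 0.8, impute_majority_frac = 1,
                        suspicious_frac = 0.1) {
  stopifnot(k >= 1, length(order) == length(pos_cM))
  inf <- informative_markers(geno)
  origins <- origins_from_calls(geno, phases)
  sing <- detect_singletons(origins, order, inf)
  susp <- flag_suspicious(sing, origins, inf, suspicious_frac)
  n_mrk <- nrow(geno$calls); n_off <- geno$n_off
  pos <- rep(NA_real_, n_mrk)
  pos[order] <- pos_cM

  # resolved origin per parent for every cell that needs fixing
  is_sing <- list(
    maternal = matrix(FALSE, n_mrk, n_off),
    paternal = matrix(FALSE, n_mrk, n_off))
  if (nrow(sing))
    for (par in c("maternal", "paternal")) {
      sp <- sing[sing$parent == par, , drop = FALSE]
      is_sing[[par]][cbind(sp$marker, sp$offspring)] <- TRUE
    }

  # cells to resolve: singletons (either meiosis) or missing calls,
  # excluding suspicious markers
  need <- is.na(geno$calls) | is_sing$maternal | is_sing$paternal
  if (length(susp)) need[susp, ] <- FALSE

  resolved <- list(
    maternal = origins$maternal, paternal = origins$paternal)
  for (par in c("maternal", "paternal")) {
    sub <- order[inf[order, par]]
    if (length(sub) < 2L) next
    subpos <- pos[sub]
    O <- origins[[par]][sub, , drop = FALSE]
    S <- is_sing[[par]][sub, , drop = FALSE]
    Nd <- need[sub, , drop = FALSE]
    for (o in seq_len(n_off)) {
      tgt <- which(Nd[, o] & inf[sub, par] &
                     (S[, o] | is.na(O[, o])))
      if (!length(tgt)) next
      ref <- which(!is.na(O[, o]) & !S[, o])
      for (t in tgt) {
        mrk <- sub[t]
        if (!length(ref)) next
        imputing <- is.na(geno$calls[mrk, o])
        if (imputing) {
          # interpolation vote: nearest voters from each side, so a cell
          # sitting on a crossover sees a mixed vote and is filtered
          kh <- max(1L, k %/% 2L)
          lft <- ref[subpos[ref] < subpos[t]]
          rgt <- ref[subpos[ref] > subpos[t]]
          lft <- lft[base::order(subpos[t] - subpos[lft])]
          rgt <- rgt[base::order(subpos[rgt] - subpos[t])]
          sel <- c(utils::head(lft, kh), utils::head(rgt, kh))
          if (!length(sel)) next
          need_frac <- impute_majority_frac
        } else {
          d <- abs(subpos[ref] - subpos[t])
          sel <- ref[base::order(d)[seq_len(min(k, length(ref)))]]
          need_frac <- majority_frac
        }
        vals <- O[sel, o]
        n1 <- sum(vals == 1L)
        frac <- max(n1, length(vals) - n1) / length(vals)
        resolved[[par]][mrk, o] <- if (frac >= need_frac) {
          if (n1 > length(vals) - n1) 1L else 0L
        } else NA_integer_                # failed vote: no replacement
      }
    }
  }

  # project resolved origins back to genotype classes
  calls <- geno$calls
  changes <- list()
  n_cor <- n_imp <- n_elim <- 0L
  cells <- which(need, arr.ind = TRUE)
  for (ci in seq_len(nrow(cells))) {
    i <- cells[ci, 1]; o <- cells[ci, 2]
    code <- geno$seg[i]
    pm <- if (is.na(phases[i, 1])) 0L else phases[i, 1]
    pp <- if (is.na(phases[i, 2])) 0L else phases[i, 2]
    newcl <- class_from_origins(resolved$maternal[i, o],
                                resolved$paternal[i, o], code, pm, pp)
    old <- calls[i, o]
    was_sing <- is_sing$maternal[i, o] || is_sing$paternal[i, o]
    if (!is.na(newcl)) {
      if (is.na(old)) {
        calls[i, o] <- newcl; n_imp <- n_imp + 1L
        changes[[length(changes) + 1L]] <-
          data.frame(offspring = o, marker = geno$marker_ids[i],
                     old = NA_integer_, new = newcl,
                     reason = "imputed", stringsAsFactors = FALSE)
      } else if (newcl != old) {
        calls[i, o] <- newcl; n_cor <- n_cor + 1L
        changes[[length(changes) + 1L]] <-
          data.frame(offspring = o, marker = geno$marker_ids[i],
                     old = old, new = newcl,
                     reason = "corrected", stringsAsFactors = FALSE)
      }
    } else if (was_sing && !is.na(old)) {
      # the singleton disagrees with both flanking loci but the vote
      # produced no replacement class: eliminate it from the data
      calls[i, o] <- NA_integer_; n_elim <- n_elim + 1L
      changes[[length(changes) + 1L]] <-
        data.frame(offspring = o, marker = geno$marker_ids[i],
                   old = old, new = NA_integer_,
                   reason = "eliminated", stringsAsFactors = FALSE)
    }
  }
  changes <- if (length(changes)) do.call(rbind, changes) else
    data.frame(offspring = integer(0), marker = character(0),
               old = integer(0), new = integer(0),
               reason = character(0), stringsAsFactors = FALSE)
  list(geno = fs_geno(calls, geno$seg, geno$marker_ids),
       report = list(
         n_corrected = n_cor, n_imputed = n_imp, n_eliminated = n_elim,
         n_flagged_suspicious = length(susp),
         singleton_count = nrow(sing),
         singleton_frac = attr(susp, "singleton_frac"),
         suspicious = geno$marker_ids[susp],
         changes = changes))
}
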