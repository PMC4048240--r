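# End-to-end pipeline: grouping -> phasing -> iterative ordering and
# error correction -> final multipoint distances -> evaluation.

#' Pipeline configuration
#'
#' @param target_groups desired number of linkage groups (chromosome
#'   number), or a range.
#' @param min_group_size smallest retained group ([scan_and_simplify()]).
#' @param lod_grid LOD threshold grid for grouping.
#' @param ordering an [ordering_config()].
#' @param k,majority_frac,impute_majority_frac,suspicious_frac correction
#'   parameters ([knn_correct()]).
#' @param n_outer_rounds rounds of ordering + correction (default 4, with
#'   early stop once fewer than `min_change_frac` of the cells change).
#' @param min_change_frac early-stop threshold (fraction of cells).
#' @param min_informative,phase_lod_min phasing parameters
#'   ([anchor_phases()]).
#' @param seed integer seed driving every stochastic stage.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(target_groups = 1, min_group_size = NULL,
                            lod_grid = seq(2, 20, by = 0.5),
                            ordering = ordering_config(),
                            k = 5, majority_frac = 0.8,
                            impute_majority_frac = 1,
                            suspicious_frac = 0.1,
                            n_outer_rounds = 4, min_change_frac = 0.001,
                            min_informative = 20, phase_lod_min = 1,
                            seed = 1L) {
  stopifnot(n_outer_rounds >= 1)
  structure(list(target_groups = target_groups,
                 min_group_size = min_group_size, lod_grid = lod_grid,
                 ordering = ordering, k = as.integer(k),
                 majority_frac = majority_frac,
                 impute_majority_frac = impute_majority_frac,
                 suspicious_frac = suspicious_frac,
                 n_outer_rounds = as.integer(n_outer_rounds),
                 min_change_frac = min_change_frac,
                 min_informative = as.integer(min_informative),
                 phase_lod_min = phase_lod_min,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full mapping pipeline
#'
#' Groups the markers, infers linkage phases per group, then iterates
#' ordering ([build_group_map()]) and kNN error correction
#' ([knn_correct()]) for up to `n_outer_rounds` rounds (early stop when
#' corrections dry up), and finally re-estimates multipoint distances on
#' the cleaned data with the last order fixed.
#'
#' @param geno observed [fs_geno()] matrix.
#' @param cfg a [pipeline_config()].
#' @return object of class `fs_pipeline_result`: list with `grouping`
#'   (from [scan_and_simplify()]), `groups` (per group: `ids`, `order`
#'   and map positions, parental maps, `phases`, corrected `geno`,
#'   per-round `log`, `reports`, final `singleton_rate`, `map_length`,
#'   `converged`), and `config`.
#' @export
run_pipeline <- function(geno, cfg = pipeline_config()) {
  stopifnot(inherits(geno, "fs_geno"))
  set.seed(cfg$seed)
  lodm <- lod_matrix(geno)
  grouping <- scan_and_simplify(lodm, cfg$target_groups,
                                cfg$min_group_size, cfg$lod_grid)
  groups <- vector("list", length(grouping$groups))
  for (gi in seq_along(grouping$groups)) {
    ids <- grouping$groups[[gi]]
    sub <- subset_markers(geno, ids)
    phases <- anchor_phases(sub, cfg$min_informative, cfg$phase_lod_min)
    cur <- sub
    log <- list(); reports <- list()
    map <- NULL
    for (round in seq_len(cfg$n_outer_rounds)) {
      map <- build_group_map(cur, phases, cfg$ordering)
      cor <- knn_correct(cur, phases, map$order, map$pos_cM, cfg$k,
                         cfg$majority_frac, cfg$impute_majority_frac,
                         cfg$suspicious_frac)
      n_changed <- cor$report$n_corrected + cor$report$n_imputed +
        cor$report$n_eliminated
      inf <- informative_markers(cur)
      org <- origins_from_calls(cur, phases)
      log[[round]] <- data.frame(
        round = round, sarf = map$sarf,
        singleton_rate = singleton_rate(org, map$order, inf),
        map_length_cM = max(map$pos_cM),
        n_changed = n_changed)
      reports[[round]] <- cor$report
      cur <- cor$geno
      if (n_changed < cfg$min_change_frac * length(cur$calls)) break
    }
    # final multipoint distances on the cleaned matrix, last order fixed
    gb <- gibbs_multipoint(map$order, cur, phases,
                           cfg$ordering$gibbs_cycles,
                           cfg$ordering$gibbs_burn,
                           cfg$ordering$r_min, cfg$ordering$r_max,
                           cfg$ordering$gibbs_prior)
    integ <- integrate_maps(map$order, gb, cfg$ordering$mapfun)
    inf <- informative_markers(cur)
    org <- origins_from_calls(cur, phases)
    groups[[gi]] <- list(
      ids = cur$marker_ids, order = map$order,
      order_ids = cur$marker_ids[map$order],
      pos_cM = integ$pos_cM,
      maternal = integ$maternal, paternal = integ$paternal,
      phases = phases, geno = cur,
      log = do.call(rbind, log), reports = reports,
      singleton_rate = singleton_rate(org, map$order, inf),
      map_length = map_length(integ),
      converged = gb$maternal$converged && gb$paternal$converged)
  }
  structure(list(grouping = grouping, groups = groups, config = cfg),
            class = "fs_pipeline_result")
}

#' @export
print.fs_pipeline_result <- function(x, ...) {
  cat(sprintf("Linkage map pipeline result: %d group(s), threshold LOD %.1f\n",
              length(x$groups), x$grouping$threshold))
  for (gi in seq_along(x$groups)) {
    g <- x$groups[[gi]]
    cat(sprintf(
      "  group %d: %d markers, %.1f cM integrated, singleton rate %.3f%%%s\n",
      gi, length(g$ids), g$map_length[["integrated"]],
      100 * g$singleton_rate,
      if (g$converged) "" else " [Gibbs not converged]"))
  }
  invisible(x)
}

#' Reassemble the corrected genome-wide genotype matrix
#'
#' @param result an `fs_pipeline_result`.
#' @param template the original observed [fs_geno()] (supplies calls for
#'   markers outside any retained group).
#' @return an [fs_geno()] with corrected calls substituted per group.
#' @export
pipeline_corrected_geno <- function(result, template) {
  calls <- template$calls
  for (g in result$groups)
    calls[g$ids, ] <- g$geno$calls
  fs_geno(calls, template$seg, template$marker_ids)
}
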