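# Linkage grouping: chi-square independence LOD + single-linkage clustering
# with dendrogram simplification (fragment deletion, descendant merging).

#' Contingency table of genotype classes for a marker pair
#'
#' @param calls_i,calls_j integer class-index vectors over the same
#'   offspring (`NA` = missing); offspring with either call missing are
#'   excluded.
#' @param nclass_i,nclass_j number of genotype classes of each marker.
#' @return integer matrix of joint class counts.
#' @export
pair_contingency <- function(calls_i, calls_j,
                             nclass_i = max(calls_i, na.rm = TRUE),
                             nclass_j = max(calls_j, na.rm = TRUE)) {
  stopifnot(length(calls_i) == length(calls_j))
  ok <- !is.na(calls_i) & !is.na(calls_j)
  if (!any(ok)) stop("uninformative pair: no jointly observed offspring",
                     call. = FALSE)
  tab <- table(factor(calls_i[ok], levels = seq_len(nclass_i)),
               factor(calls_j[ok], levels = seq_len(nclass_j)))
  matrix(as.integer(tab), nclass_i, nclass_j)
}

#' Modified independence LOD from a contingency table
#'
#' Pearson's X^2 statistic with expectations `row x col / grand`, converted
#' to a LOD-type score via `X^2 / (2 ln 10)`.  Cells with zero expected
#' count are dropped (with the degrees of freedom reduced accordingly).
#'
#' @param tab contingency table (matrix of counts).
#' @return the LOD score, with attributes `x2` and `df`.
#' @export
#' @examples
#' independence_lod(matrix(c(50, 0, 0, 50), 2))   # ~21.71
independence_lod <- function(tab) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  if (n <= 0) stop("empty table", call. = FALSE)
  rt <- rowSums(tab); ct <- colSums(tab)
  e <- outer(rt, ct) / n
  use <- e > 0
  x2 <- sum((tab[use] - e[use])^2 / e[use])
  df <- (sum(rt > 0) - 1L) * (sum(ct > 0) - 1L)
  if (df <= 0) x2 <- 0
  structure(x2 / (2 * log(10)), x2 = x2, df = max(df, 0L))
}

#' Pairwise modified-LOD matrix
#'
#' @param geno an [fs_geno()] object.
#' @return symmetric marker x marker matrix of independence LOD scores
#'   (diagonal 0).
#' @export
lod_matrix <- function(geno) {
  nclass <- vapply(geno$seg, function(s) length(seg_type(s)$classes),
                   integer(1))
  m <- pairwise_lod_cpp(geno$calls, as.integer(nclass))
  dimnames(m) <- list(geno$marker_ids, geno$marker_ids)
  m
}

#' Single-linkage groups at a LOD threshold
#'
#' Connected components of the graph whose edges join marker pairs with
#' LOD >= threshold.
#'
#' @param lod symmetric LOD matrix.
#' @param threshold minimum LOD for an edge.
#' @return list of integer vectors of marker indices (row order of `lod`),
#'   largest group first.
#' @export
single_linkage <- function(lod, threshold) {
  stopifnot(threshold >= 0)
  m <- nrow(lod)
  adj <- lod >= threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  memb <- igraph::components(g)$membership
  grps <- split(seq_len(m), memb)
  grps[order(-lengths(grps))]
}

#' Threshold scan with dendrogram simplification
#'
#' Scans an increasing LOD-threshold grid; at each threshold, components
#' smaller than `min_group_size` ("group fragments") are either merged back
#' into the large component they descend from at the previous (coarser)
#' threshold, or discarded when their ancestor contains no large component.
#' Returns the smallest threshold whose simplified component count equals
#' `target_groups` (or the closest achievable count, flagged).
#'
#' @param lod symmetric LOD matrix with marker ids as dimnames.
#' @param target_groups desired number of linkage groups (the chromosome
#'   number), or a range `c(lo, hi)`.
#' @param min_group_size smallest retained component; default 1% of the
#'   markers with a floor of 3.
#' @param grid increasing LOD thresholds to scan.
#' @return list with `threshold`, `groups` (list of marker-id vectors),
#'   `discarded` (marker ids in deleted fragments), `n_groups`, `exact`
#'   (whether the target was hit).
#' @export
scan_and_simplify <- function(lod, target_groups,
                              min_group_size = NULL,
                              grid = seq(2, 20, by = 0.5)) {
  stopifnot(all(target_groups >= 1))
  m <- nrow(lod)
  ids <- rownames(lod)
  if (is.null(ids)) ids <- as.character(seq_len(m))
  if (is.null(min_group_size))
    min_group_size <- max(3L, ceiling(0.01 * m))
  lo <- min(target_groups); hi <- max(target_groups)

  simplify_at <- function(thr, thr_prev) {
    memb <- comp_membership(lod, thr)
    sizes <- tabulate(memb)
    big <- which(sizes >= min_group_size)
    assign <- rep(NA_integer_, m)          # final group id per marker
    for (b in big) assign[memb == b] <- b
    small <- setdiff(unique(memb), big)
    if (length(small)) {
      anc <- comp_membership(lod, thr_prev)
      for (s in small) {
        mem_idx <- which(memb == s)
        a <- anc[mem_idx[1]]
        cand <- big[vapply(big, function(b)
          any(anc[memb == b] == a), logical(1))]
        if (length(cand)) {
          # merge into the largest large component of the same ancestor
          tgt <- cand[which.max(sizes[cand])]
          assign[mem_idx] <- tgt
        }                                   # else: discarded fragment
      }
    }
    assign
  }

  best <- NULL
  for (gi in seq_along(grid)) {
    thr <- grid[gi]
    # ancestors are the components one grid step coarser; at the grid
    # minimum there is no coarser view, so components already separate
    # there are fragments to delete, not descendants to merge
    thr_prev <- if (gi == 1) thr else grid[gi - 1]
    assign <- simplify_at(thr, thr_prev)
    k <- length(unique(assign[!is.na(assign)]))
    dist <- if (k >= lo && k <= hi) 0L else min(abs(k - lo), abs(k - hi))
    if (is.null(best) || dist < best$dist) {
      best <- list(thr = thr, assign = assign, k = k, dist = dist)
      if (dist == 0L) break
    }
  }
  if (best$dist > 0L)
    warning("target group count not reachable on the threshold grid; ",
            "closest achieved: ", best$k, call. = FALSE)
  grp <- split(ids[!is.na(best$assign)],
               best$assign[!is.na(best$assign)])
  grp <- unname(grp[order(-lengths(grp))])
  list(threshold = best$thr, groups = grp,
       discarded = ids[is.na(best$assign)],
       n_groups = length(grp), exact = best$dist == 0L)
}

# component membership vector at a threshold
comp_membership <- function(lod, threshold) {
  adj <- lod >= threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::components(g)$membership
}
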