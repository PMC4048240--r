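# Marker ordering: spatial sampling, simulated annealing on SARF, blocked
# Gibbs multipoint estimation, parental-map integration, radius-decreasing
# rounds.

#' Annealing schedule
#'
#' @param c0 initial acceptance-control parameter (on the recombination-
#'   fraction scale of SARF differences).
#' @param cooling multiplicative decay of the control parameter per
#'   temperature level.
#' @param moves_per_temp proposals per temperature level; default
#'   `100 * n_markers`.
#' @param stop_after_rejections stop after this many consecutive
#'   rejections; `NULL` (default) scales with problem size as
#'   `max(500, 25 * n_markers)` (with place-anywhere proposals the chance
#'   that a random move helps shrinks with n, so a flat budget stops far
#'   too early on dense groups).
#' @param max_temps maximum number of temperature levels.
#' @param c_min once the control parameter decays below this, two
#'   successive levels without improvement end the search.
#' @param window anchor the search to a reference order: relocation
#'   targets stay within +/- `window` slots of a marker's reference rank
#'   and reversal segments are at most `window` long (`NULL` =
#'   unrestricted).  On noisy data the unrestricted global SARF minimum
#'   is dominated by estimation noise ("shortcuts" through spuriously
#'   small r values); anchoring keeps the robust global seriation intact
#'   while local order is refined.
#' @return an `anneal_schedule` list.
#' @export
anneal_schedule <- function(c0 = 0.1, cooling = 0.9,
                            moves_per_temp = NULL,
                            stop_after_rejections = NULL,
                            max_temps = 60, c_min = 1e-5,
                            window = NULL) {
  stopifnot(c0 > 0, cooling > 0, cooling < 1,
            is.null(stop_after_rejections) || stop_after_rejections > 0)
  structure(list(c0 = c0, cooling = cooling,
                 moves_per_temp = moves_per_temp,
                 stop_after_rejections = stop_after_rejections,
                 max_temps = as.integer(max_temps), c_min = c_min,
                 window = window),
            class = "anneal_schedule")
}

#' Ordering configuration
#'
#' @param radius0 initial spatial-sampling radius (recombination-fraction
#'   units).
#' @param radius_factor multiplicative radius decrease per map-building
#'   round.
#' @param radius_floor radius at which all remaining markers are added.
#' @param n_cycles annealing + Gibbs cycles per round (the "three to four
#'   cycles").
#' @param schedule an [anneal_schedule()].
#' @param gibbs_cycles,gibbs_burn Gibbs sweeps and burn-in per call.
#' @param gibbs_refresh refresh the pairwise matrices along the current
#'   map with multipoint interval estimates between cycles (default
#'   FALSE: on noisy data the refreshed entries are keyed to a possibly
#'   wrong intermediate adjacency and degrade the subsequent annealing).
#' @param gibbs_prior Beta prior weight for the interval-r update; small
#'   values keep zero-crossover intervals from inflating dense maps.
#' @param anchor_window anchoring window for full-set annealing (slots
#'   around the geodesic-seriation rank; see [anneal_schedule()]).  The
#'   widely spaced skeleton is annealed unrestricted.
#' @param r_min,r_max clamps for recombination fractions.
#' @param min_pair_n minimum jointly determinable meioses for a two-point
#'   entry.
#' @param mapfun mapping function for cM positions (`"haldane"` or
#'   `"kosambi"`).
#' @return an `ordering_config` list.
#' @export
ordering_config <- function(radius0 = 0.2, radius_factor = 0.5,
                            radius_floor = 0.01, n_cycles = 3,
                            schedule = anneal_schedule(),
                            gibbs_cycles = 30, gibbs_burn = 10,
                            gibbs_refresh = FALSE, gibbs_prior = 0.1,
                            anchor_window = 10L,
                            r_min = 1e-4, r_max = 0.499,
                            min_pair_n = 20,
                            mapfun = c("haldane", "kosambi")) {
  structure(list(radius0 = radius0, radius_factor = radius_factor,
                 radius_floor = radius_floor,
                 n_cycles = as.integer(n_cycles), schedule = schedule,
                 gibbs_cycles = as.integer(gibbs_cycles),
                 gibbs_burn = as.integer(gibbs_burn),
                 gibbs_refresh = isTRUE(gibbs_refresh),
                 gibbs_prior = gibbs_prior,
                 anchor_window = as.integer(anchor_window),
                 r_min = r_min, r_max = r_max,
                 min_pair_n = as.integer(min_pair_n),
                 mapfun = match.arg(mapfun)),
            class = "ordering_config")
}

# Spectral seriation of the combined pairwise matrix: markers are ordered
# by the Fiedler vector (second-smallest eigenvector of the graph
# Laplacian) of a similarity kernel on the Haldane distances.  This uses
# every pairwise entry at once, so the global arrangement is robust both
# to per-pair estimation noise and to isolated outlier entries that would
# shortcut a nearest-neighbour geodesic.  Used to initialise and anchor
# the annealer.
mds_seriation <- function(r_comb, mapfun = "haldane", sigma = NULL) {
  n <- nrow(r_comb)
  if (n <= 2L) return(seq_len(n))
  d <- r_to_cM(pmin(fill_r(r_comb), 0.45), mapfun)
  # kernel bandwidth: the median pairwise distance adapts the decay to
  # the group's extent and to noise-inflated distances
  if (is.null(sigma)) sigma <- max(stats::median(d[upper.tri(d)]), 1)
  S <- exp(-d / sigma)
  diag(S) <- 0
  L <- diag(rowSums(S)) - S
  ev <- eigen(L, symmetric = TRUE)
  base::order(ev$vectors[, n - 1L])
}

# Greedy nearest-neighbour chain: a cheap seriation used to initialise
# the annealer.  Starts from the marker with the largest total distance
# (likely terminal) and repeatedly appends the closest unvisited marker.
nn_chain_order <- function(idx, r_comb) {
  if (length(idx) <= 2L) return(idx)
  r <- r_comb[idx, idx, drop = FALSE]
  r[is.na(r)] <- 0.5
  start <- which.max(rowSums(r))
  ord <- integer(length(idx))
  used <- logical(length(idx))
  ord[1] <- start; used[start] <- TRUE
  for (k in 2:length(idx)) {
    d <- r[ord[k - 1L], ]
    d[used] <- Inf
    nxt <- which.min(d)
    ord[k] <- nxt; used[nxt] <- TRUE
  }
  idx[ord]
}

# segregation-code selection priority: full cross > hkxhk > test cross
seg_priority <- function(seg) {
  ifelse(seg %in% c("abxcd", "efxeg"), 1L,
         ifelse(seg == "hkxhk", 2L, 3L))
}

#' Spatial sampling of mutually distant markers
#'
#' Repeatedly selects a random marker (full-cross types first, then
#' `hkxhk`, then test-cross types) and removes all candidates closer than
#' `radius` (recombination fraction) to it, until no candidates remain.
#' All retained pairwise distances are >= `radius`; unknown distances
#' (`NA`) never exclude a marker.
#'
#' @param r_comb combined recombination-fraction matrix.
#' @param radius sampling radius in `(0, 0.5]`.
#' @param seg segregation codes (per row of `r_comb`).
#' @param candidates marker indices eligible for selection (default: all).
#' @param exclude_near additionally remove candidates closer than `radius`
#'   to any of these (already mapped) markers.
#' @return integer vector of selected marker indices, in selection order.
#' @export
spatial_sample <- function(r_comb, radius, seg,
                           candidates = seq_len(nrow(r_comb)),
                           exclude_near = integer(0)) {
  stopifnot(radius > 0, radius <= 0.5, length(candidates) >= 1)
  pri <- seg_priority(seg)
  remaining <- candidates
  for (x in exclude_near) {
    d <- r_comb[x, remaining]
    remaining <- remaining[is.na(d) | d >= radius]
  }
  picked <- integer(0)
  while (length(remaining)) {
    top <- remaining[pri[remaining] == min(pri[remaining])]
    x <- if (length(top) == 1L) top else top[sample.int(length(top), 1)]
    picked <- c(picked, x)
    remaining <- setdiff(remaining, x)
    if (length(remaining)) {
      d <- r_comb[x, remaining]
      remaining <- remaining[is.na(d) | d >= radius]
    }
  }
  picked
}

# replace NA entries by a default distance (0.5: unlinked)
fill_r <- function(r, default = 0.5) {
  r[is.na(r)] <- default
  diag(r) <- 0
  r
}

#' Sum of adjacent recombination fractions (SARF)
#'
#' The ordering objective: the sum of recombination fractions between
#' adjacent markers along the maternal sub-order plus the same along the
#' paternal sub-order (each parent's sub-order is the restriction of the
#' candidate order to the markers informative in that parent).
#'
#' @param order integer vector of marker indices.
#' @param rm,rp per-parent recombination-fraction matrices (`NA` allowed;
#'   treated as 0.5).
#' @param infm,infp logical vectors: marker informative in the maternal /
#'   paternal parent.
#' @return the SARF value (unitless, >= 0, reversal-invariant).
#' @export
sarf <- function(order, rm, rp, infm, infp) {
  sarf_cpp(as.integer(order) - 1L, fill_r(rm), fill_r(rp), infm, infp)
}

#' Simulated-annealing marker ordering
#'
#' Metropolis search over orders with the move "place a random locus into
#' a random position": a proposal is accepted if it does not increase SARF,
#' else with probability `exp(-delta / c)`; `c` cools according to the
#' schedule.  Returns the best order visited.
#'
#' @inheritParams sarf
#' @param schedule an [anneal_schedule()].
#' @param ref_order reference order anchoring the search when the
#'   schedule has a `window` (default: the initial order).
#' @return list with `order` (marker indices) and `sarf`.
#' @export
anneal_order <- function(order, rm, rp, infm, infp,
                         schedule = anneal_schedule(),
                         ref_order = order) {
  stopifnot(length(order) >= 1)
  mpt <- schedule$moves_per_temp
  if (is.null(mpt)) mpt <- 100L * length(order)
  sar <- schedule$stop_after_rejections
  if (is.null(sar)) sar <- max(500L, 25L * length(order))
  win <- schedule$window
  if (is.null(win)) win <- 0L
  ref <- integer(nrow(rm))
  ref[ref_order] <- seq_along(ref_order) - 1L
  res <- anneal_cpp(as.integer(order) - 1L, fill_r(rm), fill_r(rp),
                    infm, infp, schedule$c0, schedule$cooling,
                    as.integer(mpt), as.integer(sar),
                    schedule$max_temps, schedule$c_min, as.integer(win),
                    ref)
  list(order = res$order + 1L, sarf = res$sarf)
}

#' Blocked Gibbs multipoint estimation
#'
#' For a fixed marker order, alternates exact joint sampling of each
#' offspring's complete inheritance vector per parental meiosis (forward
#' filtering / backward sampling over the hidden chromatid-origin chain,
#' integrating over missing and origin-ambiguous calls) with conjugate
#' Beta draws of each interval's recombination fraction given the sampled
#' crossover counts.
#'
#' @param order marker indices defining the map order.
#' @param geno an [fs_geno()] object.
#' @param phases phase matrix from [anchor_phases()].
#' @param n_cycles,burn_in Gibbs sweeps and burn-in.
#' @param r_min,r_max clamps for interval recombination fractions.
#' @param prior_a Beta prior weight of the conjugate interval-r update
#'   (`Beta(prior_a + k, prior_a + m - k)`).
#' @return list with one element per parent (`maternal`, `paternal`), each
#'   holding `markers` (the parent's sub-order), `interval_r` (posterior
#'   means), `mc_se` (Monte-Carlo standard errors), `origin_prob`
#'   (posterior probability of chromatid B per marker x offspring), and
#'   `converged` (split-chain diagnostic; `FALSE` flags a non-converged
#'   chain).
#' @export
gibbs_multipoint <- function(order, geno, phases, n_cycles = 30,
                             burn_in = 10, r_min = 1e-4, r_max = 0.499,
                             prior_a = 0.1) {
  org <- origins_from_calls(geno, phases)
  inf <- informative_markers(geno)
  out <- list()
  for (par in c("maternal", "paternal")) {
    sub <- order[inf[order, par]]
    if (length(sub) < 2L) {
      out[[par]] <- list(markers = sub, interval_r = numeric(0),
                         mc_se = numeric(0),
                         origin_prob = matrix(0.5, length(sub),
                                              geno$n_off),
                         converged = TRUE)
      next
    }
    obs <- org[[par]][sub, , drop = FALSE]
    res <- gibbs_chain_cpp(obs, rep(0.1, length(sub) - 1L),
                           as.integer(n_cycles), as.integer(burn_in),
                           r_min, r_max, prior_a)
    draws <- res$r_draws
    kept <- nrow(draws)
    # report the posterior mean crossover rate (mean sampled count / m):
    # unlike the mean of the Beta draws it carries no prior pseudo-count,
    # which would otherwise inflate dense maps by ~prior_a/m per interval
    r_mean <- pmin(pmax(res$k_mean / geno$n_off, r_min), r_max)
    mc_se <- apply(draws, 2, stats::sd) / sqrt(kept)
    h1 <- colMeans(draws[seq_len(kept %/% 2), , drop = FALSE])
    h2 <- colMeans(draws[(kept %/% 2 + 1):kept, , drop = FALSE])
    # split-chain diagnostic on the posterior-sd scale (a crude R-hat):
    # genuine Monte-Carlo wobble of half-means stays well under the draw
    # spread, while a stuck or drifting chain separates its halves
    conv <- all(abs(h1 - h2) <=
                  1.5 * apply(draws, 2, stats::sd) + 1e-3)
    out[[par]] <- list(markers = sub, interval_r = r_mean, mc_se = mc_se,
                       origin_prob = res$origin_prob, converged = conv)
  }
  out
}

# cM positions of a parental map from its interval recombination fractions
map_positions <- function(interval_r, mapfun = "haldane") {
  c(0, cumsum(r_to_cM(interval_r, mapfun)))
}

#' Integrate the two parental maps
#'
#' Builds integrated cM positions for the complete order: each adjacent
#' interval's distance pools the parental multipoint map distances of the
#' two flanking markers over the meioses in which both are informative
#' (mean of the available parental distances; test-cross stretches fall
#' back to the single informative parent).
#'
#' @param order the full marker order (indices).
#' @param gibbs result of [gibbs_multipoint()] on that order.
#' @param mapfun mapping function for cM conversion.
#' @return list with `order`, `pos_cM` (integrated), and `maternal` /
#'   `paternal` parental maps (`markers`, `interval_r`, `pos_cM`).
#' @export
integrate_maps <- function(order, gibbs, mapfun = "haldane") {
  pmap <- list()
  pos_par <- list()
  for (par in c("maternal", "paternal")) {
    g <- gibbs[[par]]
    pos <- map_positions(g$interval_r, mapfun)
    pmap[[par]] <- list(parent = par, markers = g$markers,
                        interval_r = g$interval_r, pos_cM = pos)
    pp <- rep(NA_real_, max(order))
    pp[g$markers] <- pos
    pos_par[[par]] <- pp
  }
  n <- length(order)
  d <- numeric(n - 1)
  for (k in seq_len(n - 1)) {
    a <- order[k]; b <- order[k + 1]
    dm <- abs(pos_par$maternal[a] - pos_par$maternal[b])
    dp <- abs(pos_par$paternal[a] - pos_par$paternal[b])
    avail <- c(dm, dp)[!is.na(c(dm, dp))]
    d[k] <- if (length(avail)) mean(avail) else 0
  }
  list(order = order, pos_cM = c(0, cumsum(d)),
       maternal = pmap$maternal, paternal = pmap$paternal)
}

#' Build the map of one linkage group
#'
#' Radius-decreasing rounds of the ordering engine: spatial sampling of a
#' skeleton at the current radius, then `n_cycles` cycles of simulated
#' annealing and blocked Gibbs multipoint estimation (the multipoint
#' interval estimates refresh the pairwise matrix used by the next
#' annealing pass), then insertion of newly sampled markers at a reduced
#' radius, until every marker is placed.
#'
#' @param geno an [fs_geno()] object holding one linkage group.
#' @param phases phase matrix from [anchor_phases()].
#' @param config an [ordering_config()].
#' @param seed optional integer seed.
#' @return list with `order` (marker indices), `ids`, `pos_cM` (integrated
#'   positions), `maternal`, `paternal` (parental maps), `sarf`,
#'   `gibbs` (final multipoint result), `converged`, and `rounds` (per-
#'   round log of radius, sample size and SARF).
#' @export
build_group_map <- function(geno, phases, config = ordering_config(),
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(geno$calls)
  inf <- informative_markers(geno)
  if (n == 1L) {
    gb <- gibbs_multipoint(1L, geno, phases, config$gibbs_cycles,
                           config$gibbs_burn, config$r_min, config$r_max,
                           config$gibbs_prior)
    return(list(order = 1L, ids = geno$marker_ids, pos_cM = 0,
                maternal = list(parent = "maternal", markers = integer(0),
                                interval_r = numeric(0), pos_cM = numeric(0)),
                paternal = list(parent = "paternal", markers = integer(0),
                                interval_r = numeric(0), pos_cM = numeric(0)),
                sarf = 0, gibbs = gb, converged = TRUE,
                rounds = data.frame()))
  }
  tp <- twopoint_matrices(geno, phases, config$min_pair_n, config$r_min)
  rm_f <- fill_r(tp$maternal$r)
  rp_f <- fill_r(tp$paternal$r)
  infm <- inf[, 1]; infp <- inf[, 2]

  master <- mds_seriation(tp$combined, config$mapfun)
  mrank <- integer(n)
  mrank[master] <- seq_len(n)
  radius <- config$radius0
  skel <- spatial_sample(tp$combined, radius, geno$seg)
  order <- skel[base::order(mrank[skel])]
  rounds <- list()
  gb <- NULL
  skeleton_round <- TRUE
  repeat {
    # the widely spaced skeleton has enough r contrast for a free global
    # search; once close markers join, annealing is anchored to the
    # geodesic seriation so estimation noise cannot scramble the global
    # arrangement (see anneal_schedule 'window')
    sched <- config$schedule
    if (is.null(sched$window))
      sched$window <- if (skeleton_round) 0L else config$anchor_window
    skeleton_round <- FALSE
    for (cyc in seq_len(config$n_cycles)) {
      ann <- anneal_order(order, rm_f, rp_f, infm, infp, sched,
                          ref_order = order[base::order(mrank[order])])
      order <- ann$order
      gb <- gibbs_multipoint(order, geno, phases, config$gibbs_cycles,
                             config$gibbs_burn, config$r_min,
                             config$r_max, config$gibbs_prior)
      # refresh pairwise entries along the map with multipoint estimates
      if (!config$gibbs_refresh) next
      for (par in c("maternal", "paternal")) {
        sub <- gb[[par]]$markers
        if (length(sub) >= 2L) {
          ii <- sub[-length(sub)]; jj <- sub[-1]
          tgt <- if (par == "maternal") "rm_f" else "rp_f"
          mat <- get(tgt)
          mat[cbind(ii, jj)] <- gb[[par]]$interval_r
          mat[cbind(jj, ii)] <- gb[[par]]$interval_r
          assign(tgt, mat)
        }
      }
    }
    rounds[[length(rounds) + 1L]] <-
      data.frame(radius = radius, n_mapped = length(order),
                 sarf = sarf_cpp(order - 1L, rm_f, rp_f, infm, infp))
    unmapped <- setdiff(seq_len(n), order)
    if (!length(unmapped)) break
    radius <- max(radius * config$radius_factor, config$radius_floor)
    if (radius <= config$radius_floor) {
      newm <- unmapped[sample.int(length(unmapped))]
    } else {
      newm <- spatial_sample(tp$combined, radius, geno$seg,
                             candidates = unmapped,
                             exclude_near = order)
    }
    if (length(newm))
      order <- insert_by_rank(order, newm, mrank, rm_f, rp_f,
                              infm, infp)
  }
  integ <- integrate_maps(order, gb, config$mapfun)
  # orientation convention: lower-index terminal marker first
  if (order[1] > order[length(order)]) {
    order <- rev(order)
    integ <- list(order = order,
                  pos_cM = max(integ$pos_cM) - rev(integ$pos_cM),
                  maternal = reverse_pmap(integ$maternal),
                  paternal = reverse_pmap(integ$paternal))
  }
  list(order = order, ids = geno$marker_ids[order],
       pos_cM = integ$pos_cM,
       maternal = integ$maternal, paternal = integ$paternal,
       sarf = sarf_cpp(order - 1L, rm_f, rp_f, infm, infp),
       gibbs = gb,
       converged = gb$maternal$converged && gb$paternal$converged,
       rounds = do.call(rbind, rounds))
}

# Insert new markers near their master-seriation slot, choosing among
# the +/- 3 neighbouring slots by smallest SARF.
insert_by_rank <- function(order, newm, mrank, rm, rp, infm, infp) {
  for (x in newm[base::order(mrank[newm])]) {
    s0 <- sum(mrank[order] < mrank[x])
    lo <- max(0L, s0 - 3L); hi <- min(length(order), s0 + 3L)
    best_s <- s0; best_v <- Inf
    for (s in lo:hi) {
      cand <- append(order, x, after = s)
      v <- sarf_cpp(as.integer(cand) - 1L, rm, rp, infm, infp)
      if (v < best_v) { best_v <- v; best_s <- s }
    }
    order <- append(order, x, after = best_s)
  }
  as.integer(order)
}

reverse_pmap <- function(pm) {
  list(parent = pm$parent, markers = rev(pm$markers),
       interval_r = rev(pm$interval_r),
       pos_cM = max(c(pm$pos_cM, 0)) - rev(pm$pos_cM))
}
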