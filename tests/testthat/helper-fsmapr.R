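# Shared helpers: independent oracles and small constructors.
# Everything here is deliberately written without reusing the package's
# internal code paths, so tests compare two independent routes.

# all permutations of 1..n (n small)
perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  p <- perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, ifelse(p >= k, p + 1L, p))))
}

# brute-force SARF: explicit loop over each parent's informative
# subsequence, NA treated as 0.5
brute_sarf <- function(order, rm, rp, infm, infp) {
  one <- function(r, inf) {
    sub <- order[inf[order]]
    if (length(sub) < 2) return(0)
    tot <- 0
    for (k in seq_len(length(sub) - 1)) {
      v <- r[sub[k], sub[k + 1]]
      tot <- tot + if (is.na(v)) 0.5 else v
    }
    tot
  }
  one(rm, infm) + one(rp, infp)
}

# brute-force singleton scan straight from the definition
brute_singletons <- function(origins, order, inf) {
  hits <- 0L
  for (par in c("maternal", "paternal")) {
    sub <- order[inf[order, par]]
    O <- origins[[par]][sub, , drop = FALSE]
    if (nrow(O) < 3) next
    for (o in seq_len(ncol(O))) {
      v <- O[, o][!is.na(O[, o])]
      if (length(v) < 3) next
      for (k in 2:(length(v) - 1))
        if (v[k] != v[k - 1] && v[k] != v[k + 1]) hits <- hits + 1L
    }
  }
  hits
}

# parental allele tables, independent of the package registry
SEG_ALLELES <- list(
  abxcd = list(m = c("a", "b"), p = c("c", "d")),
  efxeg = list(m = c("e", "f"), p = c("e", "g")),
  hkxhk = list(m = c("h", "k"), p = c("h", "k")),
  nnxnp = list(m = c("n", "n"), p = c("n", "p")),
  lmxll = list(m = c("l", "m"), p = c("l", "l")))

# oracle class label from chromatid origins and phases
oracle_class <- function(code, om, op, pm = 0L, pp = 0L) {
  al <- SEG_ALLELES[[code]]
  a <- al$m[1 + bitwXor(om, pm)]
  b <- al$p[1 + bitwXor(op, pp)]
  paste0(sort(c(a, b)), collapse = "")
}

# build a test-cross (nnxnp) pair of call vectors with exactly k
# recombinant offspring out of n (coupling phase)
testcross_pair <- function(n, k) {
  o1 <- rep(0:1, length.out = n)
  o2 <- o1
  if (k > 0) o2[seq_len(k)] <- 1L - o2[seq_len(k)]
  st <- seg_type("nnxnp")$classes        # "nn", "np"
  list(calls_i = o1 + 1L, calls_j = o2 + 1L)
}

# small clean family with an fs_geno built directly from known origins
family_from_origins <- function(orig_m, orig_p, seg, phases = NULL) {
  n_mrk <- nrow(orig_m)
  if (is.null(phases)) {
    phases <- matrix(0L, n_mrk, 2)
    inf <- t(vapply(seg, function(s) seg_type(s)$informative, logical(2)))
    phases[!inf] <- NA_integer_
  }
  calls <- matrix(NA_integer_, n_mrk, ncol(orig_m))
  for (i in seq_len(n_mrk)) {
    cl <- seg_type(seg[i])$classes
    for (o in seq_len(ncol(orig_m))) {
      lab <- oracle_class(seg[i], orig_m[i, o], orig_p[i, o],
                          ifelse(is.na(phases[i, 1]), 0L, phases[i, 1]),
                          ifelse(is.na(phases[i, 2]), 0L, phases[i, 2]))
      calls[i, o] <- match(lab, cl)
    }
  }
  list(geno = fs_geno(calls, seg), phases = phases)
}

# origin chains with fixed switch probabilities per interval
sim_origin_chain <- function(n_mrk, n_off, r_intervals) {
  o <- matrix(0L, n_mrk, n_off)
  o[1, ] <- sample(0:1, n_off, replace = TRUE)
  for (j in seq_len(n_mrk - 1)) {
    sw <- runif(n_off) < r_intervals[j]
    o[j + 1, ] <- ifelse(sw, 1L - o[j, ], o[j, ])
  }
  o
}
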