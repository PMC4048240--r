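# Segregation-type semantics for an outbred full-sib (CP) family.
#
# Each marker has a segregation code describing the allelic configuration of
# the two parents.  By convention the first-listed parent is the maternal one,
# so "lmxll" segregates in the maternal parent and "nnxnp" in the paternal
# parent.  Linkage phase 0 ("coupling") means the first allele of the
# informative parent sits on chromatid A; phase 1 swaps chromatids.

SEG_CODES <- c("abxcd", "efxeg", "hkxhk", "nnxnp", "lmxll")

MISSING_CODE <- "--"

# Internal registry: parental alleles (chromatid A first under coupling),
# offspring genotype classes, expected Mendelian ratio, informativeness.
.seg_registry <- local({
  def <- function(mat, pat) {
    classes <- character(0)
    combos <- list()
    for (i in 1:2) for (j in 1:2) {
      lab <- paste0(sort(c(mat[i], pat[j])), collapse = "")
      if (!lab %in% classes) {
        classes <- c(classes, lab)
        combos[[lab]] <- list()
      }
      combos[[lab]] <- c(combos[[lab]], list(c(i, j)))
    }
    classes <- sort(classes)
    ratio <- vapply(classes, function(cl) length(combos[[cl]]), numeric(1))
    # origin (chromatid index 1=A, 2=B) of each class per parent under
    # coupling/coupling; NA when ambiguous or parent uninformative
    orig <- matrix(NA_integer_, length(classes), 2,
                   dimnames = list(classes, c("maternal", "paternal")))
    for (cl in classes) {
      ms <- unique(vapply(combos[[cl]], `[`, integer(1), 1))
      ps <- unique(vapply(combos[[cl]], `[`, integer(1), 2))
      if (length(ms) == 1L && mat[1] != mat[2]) orig[cl, 1] <- ms - 1L
      if (length(ps) == 1L && pat[1] != pat[2]) orig[cl, 2] <- ps - 1L
    }
    list(maternal_alleles = mat, paternal_alleles = pat,
         classes = classes, ratio = ratio / sum(ratio),
         informative = c(maternal = mat[1] != mat[2],
                         paternal = pat[1] != pat[2]),
         origin_coupling = orig)
  }
  list(
    abxcd = def(c("a", "b"), c("c", "d")),
    efxeg = def(c("e", "f"), c("e", "g")),
    hkxhk = def(c("h", "k"), c("h", "k")),
    nnxnp = def(c("n", "n"), c("n", "p")),
    lmxll = def(c("l", "m"), c("l", "l"))
  )
})

#' Segregation-type descriptor
#'
#' Look up the offspring genotype classes, expected Mendelian ratio and
#' parent informativeness of one of the five CP segregation types.
#'
#' @param code one of `"abxcd"`, `"efxeg"`, `"hkxhk"`, `"nnxnp"`, `"lmxll"`.
#' @return a list with elements `classes` (ordered genotype-class labels),
#'   `ratio` (expected proportions), `informative` (named logical, maternal /
#'   paternal), `maternal_alleles`, `paternal_alleles` and `origin_coupling`
#'   (class x parent matrix of chromatid origins, 0 = A, 1 = B, `NA` =
#'   undetermined, under coupling phase in both parents).
#' @export
#' @examples
#' seg_type("hkxhk")$ratio   # 1:2:1
seg_type <- function(code) {
  code <- tolower(code)
  if (!code %in% SEG_CODES)
    stop("unknown segregation code: ", code, call. = FALSE)
  .seg_registry[[code]]
}

#' Expected genotype-class counts under Mendelian segregation
#'
#' @param code segregation code (see [seg_type()]).
#' @param n number of offspring.
#' @return named numeric vector of expected counts, summing to `n`.
#' @export
expected_segregation_counts <- function(code, n) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 0)
  st <- seg_type(code)
  stats::setNames(st$ratio * n, st$classes)
}

#' Parental-origin classification of a genotype call
#'
#' Maps an offspring genotype class at one marker to the pair of parental
#' chromatid origins (maternal meiosis, paternal meiosis), given the marker's
#' segregation type and linkage phases.  Origins are coded 0 (chromatid A),
#' 1 (chromatid B) or `NA` when undeterminable: missing calls, uninformative
#' parents, and the origin-ambiguous `hk` class of `hkxhk` markers.
#'
#' @param call integer class index into `seg_type(code)$classes`, or `NA`
#'   for missing.
#' @param code segregation code.
#' @param phase_m,phase_p linkage phase (0 coupling / 1 repulsion) of the
#'   maternal / paternal parent at this marker; ignored for parents in which
#'   the marker is uninformative.
#' @return integer vector `c(maternal, paternal)` with values in
#'   `{0, 1, NA}`.
#' @export
classify_call <- function(call, code, phase_m = 0L, phase_p = 0L) {
  st <- seg_type(code)
  if (is.na(call)) return(c(maternal = NA_integer_, paternal = NA_integer_))
  if (!(call >= 1L && call <= length(st$classes)))
    stop("invalid class index ", call, " for segregation type ", code,
         call. = FALSE)
  o <- st$origin_coupling[call, ]
  if (!is.na(o[1])) o[1] <- bitwXor(o[1], as.integer(phase_m))
  if (!is.na(o[2])) o[2] <- bitwXor(o[2], as.integer(phase_p))
  stats::setNames(as.integer(o), c("maternal", "paternal"))
}

# Inverse of classify_call: genotype-class index from the pair of parental
# chromatid origins; NA when any required origin is unknown.
class_from_origins <- function(o_m, o_p, code, phase_m = 0L, phase_p = 0L) {
  st <- seg_type(code)
  if (st$informative[["maternal"]]) {
    if (is.na(o_m)) return(NA_integer_)
    am <- st$maternal_alleles[1L + bitwXor(o_m, as.integer(phase_m))]
  } else am <- st$maternal_alleles[1L]
  if (st$informative[["paternal"]]) {
    if (is.na(o_p)) return(NA_integer_)
    ap <- st$paternal_alleles[1L + bitwXor(o_p, as.integer(phase_p))]
  } else ap <- st$paternal_alleles[1L]
  lab <- paste0(sort(c(am, ap)), collapse = "")
  match(lab, st$classes)
}

# Vectorised origin computation for a whole genotype matrix.
# Returns list(maternal, paternal): marker x offspring integer matrices
# (0 = A, 1 = B, NA = undeterminable).
origins_from_calls <- function(geno, phases) {
  calls <- geno$calls
  n_mrk <- nrow(calls); n_off <- ncol(calls)
  out_m <- matrix(NA_integer_, n_mrk, n_off, dimnames = dimnames(calls))
  out_p <- matrix(NA_integer_, n_mrk, n_off, dimnames = dimnames(calls))
  for (i in seq_len(n_mrk)) {
    st <- seg_type(geno$seg[i])
    base <- st$origin_coupling
    cl <- calls[i, ]
    om <- base[, 1][cl]           # NA call index -> NA via indexing
    op <- base[, 2][cl]
    if (!is.na(phases[i, 1]) && phases[i, 1] == 1L) om <- 1L - om
    if (!is.na(phases[i, 2]) && phases[i, 2] == 1L) op <- 1L - op
    out_m[i, ] <- om
    out_p[i, ] <- op
  }
  list(maternal = out_m, paternal = out_p)
}

# Logical vectors: which markers are informative in each parent.
informative_markers <- function(geno) {
  inf <- t(vapply(geno$seg, function(s) seg_type(s)$informative, logical(2)))
  dimnames(inf) <- list(geno$marker_ids, c("maternal", "paternal"))
  inf
}
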