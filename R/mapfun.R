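# Mapping functions between recombination fraction and map distance.

#' Map-distance conversions
#'
#' Convert between recombination fraction `r` and map distance in
#' centiMorgan.  The Haldane function assumes no crossover interference
#' (consistent with the bundled simulator); Kosambi allows for positive
#' interference.
#'
#' @param d distance in cM.
#' @param r recombination fraction in `[0, 0.5)`.
#' @param fun `"haldane"` (default) or `"kosambi"`.
#' @return numeric vector of converted values.
#' @export
#' @examples
#' r_to_cM(0.2)            # 25.54 cM under Haldane
#' cM_to_r(10)             # 0.0906
r_to_cM <- function(r, fun = c("haldane", "kosambi")) {
  fun <- match.arg(fun)
  r <- pmin(r, 0.49999)
  switch(fun,
         haldane = -50 * log(1 - 2 * r),
         kosambi = 25 * log((1 + 2 * r) / (1 - 2 * r)))
}

#' @rdname r_to_cM
#' @export
cM_to_r <- function(d, fun = c("haldane", "kosambi")) {
  fun <- match.arg(fun)
  switch(fun,
         haldane = (1 - exp(-2 * d / 100)) / 2,
         kosambi = tanh(2 * d / 100) / 2)
}
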