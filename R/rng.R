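#' Derive a reproducible substream seed
#'
#' All stochastic functions in the package draw their randomness from a single
#' user-supplied integer seed. Independent generator calls (one per modality,
#' one per LUT node, one per wavelength, ...) receive their own substream seed
#' derived deterministically from the master seed and a string label, so that
#' adding or reordering calls never perturbs the draws of the others.
#'
#' The label is hashed with a polynomial rolling hash and combined with the
#' master seed by a fixed linear-congruential mix; the result is reduced to
#' the positive 31-bit range so it is always a valid R integer seed.
#'
#' @param seed integer master seed.
#' @param label character scalar naming the substream.
#' @return a positive integer seed.
#' @examples
#' split_seed(1, "kinetics/young_adult")
#' @export
split_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(label), length(label) == 1)
  # polynomial rolling hash modulo a Mersenne-adjacent prime; every
  # intermediate stays far below 2^53 so the arithmetic is exact in doubles
  h <- 0
  for (b in utf8ToInt(label)) h <- (h * 131 + b) %% 2147483629
  mixed <- (abs(seed) %% 2147483647) * 48271 + h
  as.integer(mixed %% 2147483646 + 1)
}

with_substream <- function(seed, label, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(split_seed(seed, label))
  force(code)
}
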