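# shared numeric helpers

#' Round half away from zero
#'
#' Plain commercial rounding to whole numbers: 0.5 always rounds up in
#' magnitude (`round_half_up(4.5) == 5`, `round_half_up(-4.5) == -5`),
#' unlike [round()]'s round-half-to-even. All printed percentage tables in
#' this package use this convention.
#'
#' @param x Numeric vector.
#' @return Numeric vector of whole numbers.
#' @export
#' @examples
#' round_half_up(c(0.5, 1.5, 2.49, -0.5))
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# log(sum(exp(x))) without overflow; -Inf-safe
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Sub-seed derivation: one root seed, fixed per-generator offsets, so that
# all generators are independent yet jointly reproducible. Kept < 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% .Machine$integer.max)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s].",
                  name, format(lower), format(upper)))
  }
  invisible(x)
}
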