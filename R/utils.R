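#' Half-up rounding for report display
#'
#' Base R's `round()` rounds half to even; published psychometric tables use
#' half-up rounding (e.g. 0.935 prints as 0.94), so display formatting goes
#' through this helper. Internal computation always keeps full precision.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
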