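#' Round half away from zero
#'
#' Fixed-precision rounding in which ties go away from zero (so 0.005 at two
#' decimals gives 0.01), matching how published epidemiological tables are
#' typically typeset. Base R's `round()` rounds ties to even, which cannot
#' reproduce such tables cell-for-cell.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` decimal places, ties away from zero.
#' @examples
#' round_half_up(2.345, 2) # 2.35
#' round_half_up(0.125, 2) # 0.13
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# format a number at fixed decimals with half-up rounding
fmt_fixed <- function(x, digits = 2) {
  formatC(round_half_up(x, digits), format = "f", digits = digits)
}

# "est (lo to hi)" cell formatting used by the rendered exposure table
fmt_ci <- function(est, lo, hi, digits = 2) {
  sprintf("%s (%s to %s)", fmt_fixed(est, digits),
          fmt_fixed(lo, digits), fmt_fixed(hi, digits))
}

stop_input <- function(msg, ...) abort(sprintf(msg, ...), class = "mediareach_error")
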