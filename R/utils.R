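#' @importFrom rlang %||% abort warn .data
#' @importFrom stats optimize rbinom rgeom runif setNames coef lm
#' @importFrom utils head tail
NULL

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; engagement reports conventionally
#' print percentages rounded half-up (2.25 -> 2.3 at one decimal).
#'
#' @param x numeric vector
#' @param digits decimal places to keep
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Format a proportion as "pct (num/denom)"
#'
#' @param num numerator count
#' @param denom denominator count
#' @param digits decimals for the percentage (half-up rounding)
#' @return character vector like `"61.7 (216/350)"`
#' @export
format_pct <- function(num, denom, digits = 1) {
  pct <- round_half_up(100 * num / denom, digits)
  sprintf("%s (%d/%d)", format(pct, trim = TRUE), as.integer(num), as.integer(denom))
}

# internal: stop with a classed condition so tests can target error types
stop_dhengage <- function(message, class) {
  rlang::abort(message, class = c(class, "dhengage_error"))
}

is_date <- function(x) inherits(x, "Date")
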