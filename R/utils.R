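#' @importFrom stats coef glm binomial vcov pnorm plogis qlogis rbinom rnorm
#'   runif chisq.test t.test setNames anova
#' @importFrom utils head tail
#' @import data.table
NULL

#' Null-coalescing operator
#'
#' @param x,y values; `y` is used when `x` is `NULL`.
#' @return `x` unless it is `NULL`, else `y`.
#' @name op-null-default
#' @keywords internal
#' @export
`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half up
#'
#' Rounds to `digits` decimals with exact halves rounded away from zero,
#' matching the convention used in published claims tables (base R's
#' `round()` rounds halves to even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @examples
#' round_half_up(2.25, 1) # 2.3
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  # small epsilon guards binary representation of decimal halves
  sign(x) * floor(abs(x) * m + 0.5 + sqrt(.Machine$double.eps)) / m
}

#' Percentage of a count within a group, presentation-rounded
#'
#' Computes `100 * count / n` rounded half-up to one decimal, the rounding
#' used for all prevalence and descriptive percentages in the reporting
#' tables.
#'
#' @param count numeric vector of counts.
#' @param n group size(s); must be positive.
#' @return percentages on the 0-100 scale, one decimal.
#' @examples
#' claims_pct(28974, 144703) # 20.0
#' @export
claims_pct <- function(count, n) {
  if (any(n <= 0)) stop("group size must be positive; percentage undefined")
  round_half_up(100 * count / n, 1)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

as_date_strict <- function(x, what = "date") {
  d <- as.Date(x, format = "%Y-%m-%d")
  d
}
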