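#' Weighted mean and variance
#'
#' Probability-weight moments: `sum(w*x)/sum(w)` and
#' `sum(w*(x-m)^2)/sum(w)` (no Bessel correction), the definitions used
#' throughout the package so that standardized columns have weighted
#' variance exactly 1.
#'
#' @param x numeric vector.
#' @param w positive weights, same length as `x`.
#' @return `weighted_mean`/`weighted_var` return a single number.
#' @keywords internal
#' @noRd
weighted_mean <- function(x, w) sum(w * x) / sum(w)

#' @noRd
weighted_var <- function(x, w) {
  m <- weighted_mean(x, w)
  sum(w * (x - m)^2) / sum(w)
}

#' Round half away from zero
#'
#' Base `round()` rounds half to even; summary percentages follow the
#' conventional half-up rule instead (e.g. 56.675 -> 56.68).
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
#' @examples
#' round_half_up(56.675, 2) # 56.68
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Sample skewness (third standardized moment)
#'
#' Unweighted biased estimator g1 = m3 / m2^(3/2); survey weights are
#' deliberately ignored when deciding log transforms.
#'
#' @param x numeric vector; `NA` dropped.
#' @return skewness, or `NA` for constant / too-short input.
#' @export
sample_skewness <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3L) return(NA_real_)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) return(NA_real_)
  mean((x - m)^3) / m2^1.5
}
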