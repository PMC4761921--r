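# Circular (clock-face) arithmetic helpers used throughout; phases are in
# hours on [0, period).

#' Circular difference between two phases
#'
#' Shortest distance around the clock between two phases in hours, i.e.
#' `min(|a-b|, period - |a-b|)`. Vectorised.
#'
#' @param a,b Phases in hours.
#' @param period Period in hours (default 24).
#' @return Nonnegative difference in `[0, period/2]`.
#' @examples
#' circular_diff(23.5, 0.5) # 1, wraps midnight
#' @export
circular_diff <- function(a, b, period = 24) {
  d <- abs(a - b) %% period
  pmin(d, period - d)
}

#' Weighted circular mean of phases
#'
#' Resultant-vector mean of phases in hours, optionally weighted.
#'
#' @param phases Phases in hours.
#' @param weights Optional nonnegative weights (default equal).
#' @param period Period in hours.
#' @return Mean phase in `[0, period)`, or `NA` if the resultant vector is
#'   null (e.g. two equally weighted antipodal phases).
#' @export
circular_mean <- function(phases, weights = NULL, period = 24) {
  if (length(phases) == 0L) return(NA_real_)
  if (is.null(weights)) weights <- rep(1, length(phases))
  stopifnot(length(weights) == length(phases), all(weights >= 0))
  th <- 2 * pi * phases / period
  s <- sum(weights * sin(th))
  cc <- sum(weights * cos(th))
  if (abs(s) < 1e-12 && abs(cc) < 1e-12) return(NA_real_)
  res <- (atan2(s, cc) * period / (2 * pi)) %% period
  if (period - res < 1e-9) res <- 0   # snap rounding spill back to 0
  res
}

#' Mean resultant length of a set of phases
#'
#' Concentration measure in `[0, 1]`: 1 when all phases coincide, near 0
#' for phases spread uniformly around the clock.
#'
#' @inheritParams circular_mean
#' @return Resultant length in `[0, 1]` (`NA` for empty input).
#' @export
resultant_length <- function(phases, period = 24) {
  if (length(phases) == 0L) return(NA_real_)
  th <- 2 * pi * phases / period
  sqrt(mean(sin(th))^2 + mean(cos(th))^2)
}

# Shuffle the entries of each row of a matrix independently, vectorised.
# Consumes nrow(m)*ncol(m) uniforms from the current RNG stream.
shuffle_within_rows <- function(m) {
  keys <- matrix(stats::runif(length(m)), nrow(m), ncol(m))
  o <- order(row(m), keys)
  matrix(m[o], nrow(m), ncol(m), byrow = TRUE,
         dimnames = dimnames(m))
}

# Smallest positive p-value admitted before log2 transforms; keeps the
# consistency score finite for numerically zero p-values.
P_FLOOR <- 1e-300
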