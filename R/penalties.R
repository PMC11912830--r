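# Quadratic roughness penalties on the log trajectory.

#' Curvature penalty (sum of squared second differences)
#'
#' Hodrick-Prescott-style smoothing term: the sum over all interior positions
#' of the squared second difference of the sequence. Zero for any affine
#' sequence.
#'
#' @param x numeric sequence (length >= 3).
#' @return non-negative scalar.
#' @export
penalty_curvature <- function(x) {
  n <- length(x)
  if (n < 3L) stop_domain("curvature penalty needs length >= 3")
  d2 <- x[1:(n - 2)] - 2 * x[2:(n - 1)] + x[3:n]
  sum(d2^2)
}

# Gradient of penalty_curvature.
penalty_curvature_grad <- function(x) {
  n <- length(x)
  d2 <- x[1:(n - 2)] - 2 * x[2:(n - 1)] + x[3:n]
  g <- numeric(n)
  g[1:(n - 2)] <- g[1:(n - 2)] + 2 * d2
  g[2:(n - 1)] <- g[2:(n - 1)] - 4 * d2
  g[3:n] <- g[3:n] + 2 * d2
  g
}

#' Gaussian positional decay weights
#'
#' Weights `w_t = exp(-9 (t - Tmax)^2 / (2 Tmax^2))` for `t = 0 .. Tmax`
#' (length `Tmax + 1`): near zero at `t = 0` (`exp(-4.5)`), exactly 1 at
#' `t = Tmax`, strictly increasing. Downweights the first-difference penalty
#' near the present, where the IBD signal is strong, and lets it dominate deep
#' in time where the signal has faded.
#'
#' @param Tmax positive integer.
#' @return numeric vector of length `Tmax + 1`.
#' @export
decay_weights <- function(Tmax) {
  if (Tmax < 1) stop_domain("Tmax must be >= 1")
  t <- 0:Tmax
  exp(-9 * (t - Tmax)^2 / (2 * Tmax^2))
}

#' First-difference penalty with positional weights
#'
#' `sum_t w_t (x[t] - x[t-1])^2` over successive differences; `w` must have
#' the same length as `x` (its first entry is unused).
#'
#' @param x numeric sequence.
#' @param w weight sequence, `length(w) == length(x)`.
#' @return non-negative scalar.
#' @export
penalty_decayed_diff <- function(x, w) {
  if (length(w) != length(x)) stop_domain("weights and sequence lengths differ")
  n <- length(x)
  if (n < 2L) return(0)
  d <- x[-1] - x[-n]
  sum(w[-1] * d^2)
}

penalty_decayed_diff_grad <- function(x, w) {
  n <- length(x)
  g <- numeric(n)
  if (n < 2L) return(g)
  d <- x[-1] - x[-n]
  wd <- 2 * w[-1] * d
  g[-1] <- g[-1] + wd
  g[-n] <- g[-n] - wd
  g
}
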