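#' Box-Cox power transform
#'
#' \eqn{y = ((x + shift)^\lambda - 1)/\lambda} for \eqn{\lambda \neq 0} and
#' \eqn{y = \log(x + shift)} for \eqn{\lambda = 0}. Strictly increasing in
#' `x` for any `lambda`.
#'
#' @param x Numeric vector; `x + shift` must be positive.
#' @param lambda Power exponent.
#' @param shift Additive offset applied before transformation.
#' @return Transformed numeric vector.
#' @export
boxcox_transform <- function(x, lambda, shift = 0) {
  xs <- x + shift
  if (any(xs <= 0)) abort("x + shift must be positive")
  if (abs(lambda) < 1e-12) log(xs) else (xs^lambda - 1) / lambda
}

# profile log-likelihood of the Box-Cox model at a fixed lambda
boxcox_loglik <- function(xs, lambda) {
  n <- length(xs)
  y <- if (abs(lambda) < 1e-12) log(xs) else (xs^lambda - 1) / lambda
  s2 <- mean((y - mean(y))^2)
  -n / 2 * log(s2) + (lambda - 1) * sum(log(xs))
}

#' Fit an optimized Box-Cox transformation to control samples
#'
#' Chooses the power `lambda` maximizing the Box-Cox profile log-likelihood
#' of the (shifted) sample over a grid \eqn{\lambda \in [-3, 3]} in steps of
#' 0.01. Endpoints that can be zero or negative (startle differences,
#' habituation slopes) are handled by a data-driven shift,
#' `max(0, 1e-6 - min(x))`, which makes every shifted value positive.
#' Likelihood ties are broken toward the `lambda` closest to 1 (no
#' transformation).
#'
#' @param values Numeric vector of control endpoint samples; at least 20
#'   finite values with nonzero variance.
#' @return A list with elements `lambda`, `shift`, and `loglik` (the profile
#'   log-likelihood at the optimum).
#' @examples
#' set.seed(1)
#' fit_boxcox(exp(rnorm(100, 3, 0.5)))$lambda
#' @export
fit_boxcox <- function(values) {
  if (length(values) < 20) abort("insufficient controls (need >= 20 samples)")
  if (any(!is.finite(values))) abort("control values must all be finite")
  if (var(values) <= 0) abort("control values have zero variance")
  shift <- max(0, eps_pos - min(values))
  xs <- values + shift
  grid <- seq(-3, 3, by = 0.01)
  ll <- vapply(grid, function(l) boxcox_loglik(xs, l), numeric(1))
  best <- max(ll)
  cand <- grid[ll >= best - 1e-9]
  lambda <- cand[which.min(abs(cand - 1))]
  list(lambda = lambda, shift = shift, loglik = best)
}
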