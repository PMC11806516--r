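# Box-Cox machinery: the forward/inverse transform pair and profile-likelihood
# estimation of the exponent from pooled replicate measurements.

#' Box-Cox transformation and its inverse
#'
#' The one-parameter Box-Cox family used throughout the measurement-error
#' model: `f(x) = (x^lambda - 1)/lambda` for `lambda != 0` and `log(x)` for
#' `lambda == 0`. The inverse is `(lambda*y + 1)^(1/lambda)` (resp. `exp(y)`).
#' The two are mutual inverses on their domains: `x > 0` for the forward
#' transform, `lambda*y + 1 > 0` for the inverse.
#'
#' @param x positive numeric vector.
#' @param y numeric vector on the transformed scale.
#' @param lambda scalar exponent (dimensionless).
#' @return Numeric vector of the same length as the input.
#' @examples
#' box_cox(7.3, 0.35)
#' box_cox_inv(box_cox(7.3, 0.35), 0.35)
#' @export
box_cox <- function(x, lambda) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    abort_mepsim("box_cox requires strictly positive finite x", "domain")
  }
  if (abs(lambda) < 1e-12) log(x) else (x^lambda - 1) / lambda
}

#' @rdname box_cox
#' @export
box_cox_inv <- function(y, lambda) {
  if (any(!is.finite(y))) abort_mepsim("box_cox_inv requires finite y", "domain")
  if (abs(lambda) < 1e-12) return(exp(y))
  base <- lambda * y + 1
  if (any(base <= 0)) {
    abort_mepsim(
      sprintf("box_cox_inv domain violation: lambda*y + 1 <= 0 for %d value(s)",
              sum(base <= 0)), "domain")
  }
  base^(1 / lambda)
}

# Profile log-likelihood of the Box-Cox exponent for an intercept-only normal
# model of the pooled transformed values. Up to constants:
#   l(lambda) = -n/2 * log(sigma2_hat(lambda)) + (lambda - 1) * sum(log x)
bc_profile_loglik <- function(lambda, x, sum_log_x = sum(log(x))) {
  n <- length(x)
  z <- if (abs(lambda) < 1e-12) log(x) else (x^lambda - 1) / lambda
  s2 <- mean((z - mean(z))^2)
  -n / 2 * log(s2) + (lambda - 1) * sum_log_x
}

#' Estimate the Box-Cox exponent from pooled replicates
#'
#' Profile-likelihood estimate of the Box-Cox exponent that best normalises
#' the pooled measurements (all persons, all replicates, one dietary
#' component at a time). The exponent is located on a grid over
#' `[lower, upper]` (step 0.01) and then refined by golden-section search
#' ([stats::optimize()]) in the bracketing interval.
#'
#' @param x strictly positive measurements: a vector, or an `n x k` matrix of
#'   replicates that is pooled.
#' @param lower,upper search bounds for the exponent.
#' @return The estimated exponent (scalar).
#' @export
estimate_lambda <- function(x, lower = -1, upper = 2) {
  x <- as.numeric(x)
  if (any(!is.finite(x)) || any(x <= 0)) {
    abort_mepsim("estimate_lambda requires strictly positive measurements", "domain")
  }
  if (length(x) < 30) {
    abort_mepsim("estimate_lambda needs at least 30 pooled values", "spec")
  }
  slx <- sum(log(x))
  grid <- seq(lower, upper, by = 0.01)
  ll <- vapply(grid, bc_profile_loglik, numeric(1), x = x, sum_log_x = slx)
  i <- which.max(ll)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  if (lo == hi) return(grid[i])
  stats::optimize(bc_profile_loglik, c(lo, hi), x = x, sum_log_x = slx,
                  maximum = TRUE, tol = 1e-6)$maximum
}
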