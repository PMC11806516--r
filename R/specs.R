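# Domain types: the measurement-error model (replicate generator) and the
# outcome model. Both are plain validated lists with S3 classes.

#' Specify the replicate measurement-error model
#'
#' Describes how error-prone replicate measurements of p dietary components
#' arise. On a Box-Cox transformed (additive) scale, the j-th replicate for a
#' person is `beta0 + betaZ %*% Z + u + eps_j`, where `u ~ N(0, Sigma_u)` is
#' the between-person effect (drawn once per person) and
#' `eps_j ~ N(0, Sigma_eps)` is the within-person day-to-day error (drawn
#' independently per replicate). What is *observed* depends on `observe`:
#'
#' * `"boxcox"` (default): the observed intake is the inverse Box-Cox
#'   transform of the additive value, `X* = (lambda*a + 1)^(1/lambda)`.
#'   `lambda = 1` is interpreted as the identity transform, giving the
#'   classical additive model `X* = X + eps` on the raw scale.
#' * `"additive"`: the additive value itself is observed (the transform then
#'   only enters the definition of true usual intake). Mainly a diagnostic
#'   mode; moment identities (covariance `Sigma_u + Sigma_eps`, cross-replicate
#'   covariance `Sigma_u`) hold exactly on this scale.
#'
#' @param lambda Box-Cox exponent, recycled to length `p`. `1` means identity.
#' @param beta0 per-component intercept on the transformed scale (length p).
#' @param betaZ `p x q` matrix of error-free covariate effects on the
#'   transformed scale (or `NULL` when `q = 0`).
#' @param Sigma_u,Sigma_eps `p x p` between-person and within-person
#'   covariance matrices (transformed scale); must be symmetric PSD.
#' @param observe observation scale, `"boxcox"` or `"additive"`.
#' @return An object of class `me_error_spec`.
#' @export
error_model_spec <- function(lambda, beta0, betaZ = NULL, Sigma_u, Sigma_eps,
                             observe = c("boxcox", "additive")) {
  observe <- match.arg(observe)
  p <- length(beta0)
  if (p < 1) abort_mepsim("at least one error-prone component is required", "spec")
  Sigma_u <- as.matrix(Sigma_u); Sigma_eps <- as.matrix(Sigma_eps)
  check_psd(Sigma_u, "Sigma_u"); check_psd(Sigma_eps, "Sigma_eps")
  if (nrow(Sigma_u) != p || nrow(Sigma_eps) != p) {
    abort_mepsim("covariance dimensions must match length(beta0)", "spec")
  }
  if (is.null(betaZ)) betaZ <- matrix(0, p, 0)
  betaZ <- as.matrix(betaZ)
  if (nrow(betaZ) != p) abort_mepsim("betaZ must have one row per component", "spec")
  lambda <- rep_len(lambda, p)
  structure(
    list(p = p, q = ncol(betaZ), lambda = lambda, beta0 = as.numeric(beta0),
         betaZ = betaZ, Sigma_u = Sigma_u, Sigma_eps = Sigma_eps,
         observe = observe),
    class = "me_error_spec")
}

# Model transform f and inverse; lambda == 1 is the identity (raw additive).
f_model <- function(x, lambda) {
  if (abs(lambda - 1) < 1e-12) x else box_cox(x, lambda)
}
f_model_inv <- function(y, lambda) {
  if (abs(lambda - 1) < 1e-12) y else box_cox_inv(y, lambda)
}

#' @export
print.me_error_spec <- function(x, ...) {
  cat(sprintf(
    "<me_error_spec> p = %d, q = %d, lambda = %s, observe = %s\n",
    x$p, x$q, paste(signif(x$lambda, 3), collapse = "/"), x$observe))
  invisible(x)
}

#' Specify the outcome model
#'
#' The outcome follows a generalized regression model
#' `E[Y | X, Z] = g^{-1}(alpha0 + alpha' h(X, Z))` where `h` maps the
#' error-free usual intakes (and possibly covariates) to the features that
#' enter linearly, and `g^{-1}` is the inverse link.
#'
#' Available feature maps:
#' * `"linear"`: `h(X, Z) = (X, Z)`.
#' * `"ratio"`: `h(X) = X1 / X2` (two components).
#' * `"sim3_nonlinear"`: `(X1, X2, X1*X2, log X1, log X2, X1/X2, Z3)`.
#' * `"sim4_threshold"`: `(X2 * (I(X1 >= 100) - I(X3 <= 30)), log X3)`.
#'
#' @param link `"identity"` (Gaussian residual, variance `sigmaY2`) or
#'   `"expit"` (Bernoulli outcome).
#' @param feature_map one of the maps above.
#' @param alpha coefficient vector: intercept followed by one coefficient per
#'   feature-map output.
#' @param sigmaY2 residual variance (ignored for the expit link).
#' @return An object of class `me_outcome_spec`.
#' @export
outcome_model_spec <- function(link = c("identity", "expit"),
                               feature_map = c("linear", "ratio",
                                               "sim3_nonlinear", "sim4_threshold"),
                               alpha, sigmaY2 = 1) {
  link <- match.arg(link)
  feature_map <- match.arg(feature_map)
  if (sigmaY2 < 0) abort_mepsim("sigmaY2 must be nonnegative", "spec")
  structure(
    list(link = link, feature_map = feature_map, alpha = as.numeric(alpha),
         sigmaY2 = sigmaY2),
    class = "me_outcome_spec")
}

#' @export
print.me_outcome_spec <- function(x, ...) {
  cat(sprintf("<me_outcome_spec> link = %s, h = %s, %d coefficient(s)\n",
              x$link, x$feature_map, length(x$alpha)))
  invisible(x)
}

# Evaluate the feature map h(X, Z) -> n x d matrix.
outcome_features <- function(spec, X, Z = NULL) {
  X <- as.matrix(X)
  switch(spec$feature_map,
    linear = {
      if (is.null(Z) || ncol(as.matrix(Z)) == 0) X else cbind(X, as.matrix(Z))
    },
    ratio = {
      if (ncol(X) < 2) abort_mepsim("ratio feature map needs two components", "spec")
      cbind(X[, 1] / X[, 2])
    },
    sim3_nonlinear = {
      if (ncol(X) < 2 || is.null(Z) || ncol(as.matrix(Z)) < 3) {
        abort_mepsim("sim3_nonlinear needs 2 components and >= 3 covariates", "spec")
      }
      if (any(X[, 1:2] <= 0)) {
        abort_mepsim("log of non-positive component in sim3_nonlinear", "domain")
      }
      Z <- as.matrix(Z)
      cbind(X[, 1], X[, 2], X[, 1] * X[, 2], log(X[, 1]), log(X[, 2]),
            X[, 1] / X[, 2], Z[, 3])
    },
    sim4_threshold = {
      if (ncol(X) < 3) abort_mepsim("sim4_threshold needs three components", "spec")
      if (any(X[, 3] <= 0)) {
        abort_mepsim("log of non-positive component in sim4_threshold", "domain")
      }
      cbind(X[, 2] * ((X[, 1] >= 100) - (X[, 3] <= 30)), log(X[, 3]))
    })
}

#' Conditional outcome mean and outcome sampling
#'
#' `outcome_mean()` evaluates `E[Y | X, Z]` under an outcome model;
#' `generate_outcome()` adds Gaussian residual noise (identity link) or draws
#' Bernoulli outcomes (expit link).
#'
#' @param spec an [outcome_model_spec()].
#' @param X `n x p` matrix of error-free usual intakes.
#' @param Z optional `n x q` covariate matrix.
#' @param seed integer seed for the residual / Bernoulli draws.
#' @return `outcome_mean()`: n-vector of conditional means (probabilities for
#'   the expit link). `generate_outcome()`: n-vector of outcomes.
#' @export
outcome_mean <- function(spec, X, Z = NULL) {
  H <- outcome_features(spec, X, Z)
  if (length(spec$alpha) != ncol(H) + 1L) {
    abort_mepsim(sprintf("alpha has length %d but feature map produces %d features",
                         length(spec$alpha), ncol(H)), "spec")
  }
  eta <- drop(spec$alpha[1] + H %*% spec$alpha[-1])
  if (spec$link == "expit") expit(eta) else eta
}

#' @rdname outcome_mean
#' @export
generate_outcome <- function(spec, X, Z = NULL, seed = 1L) {
  mu <- outcome_mean(spec, X, Z)
  with_seed(seed, {
    if (spec$link == "expit") {
      as.numeric(stats::rbinom(length(mu), 1L, mu))
    } else if (spec$sigmaY2 == 0) {
      mu
    } else {
      mu + stats::rnorm(length(mu), 0, sqrt(spec$sigmaY2))
    }
  })
}
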