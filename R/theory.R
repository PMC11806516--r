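# Closed-form variance-reduction quantities and their Monte-Carlo verifiers.

#' Error variance after averaging on the additive scale
#'
#' When replicate errors are additive with variance `sigma2`, the average of
#' `k` replicates carries error variance `sigma2 / k`.
#'
#' @param sigma2 within-person error variance (transformed scale).
#' @param k replicate count.
#' @return The reduced variance.
#' @export
averaged_error_variance <- function(sigma2, k) {
  if (!is_count(k)) abort_mepsim("k must be a count >= 1", "spec")
  if (sigma2 < 0) abort_mepsim("sigma2 must be nonnegative", "spec")
  sigma2 / k
}

#' Equivalent single-error variance when averaging lognormal errors
#'
#' With multiplicative errors `exp(eps_j)`, `eps_j ~ N(0, sigma2)`, averaging
#' k replicates on the raw scale reduces the error variance, but by less than
#' the additive factor 1/k. This function returns the variance `s` of a
#' single Gaussian error whose lognormal `exp(eta)`, `eta ~ N(0, s)`, has the
#' same raw-scale variance as the average of the k errors: matching
#' `var[(1/k) sum exp(eps_j)] = (e^{2 sigma2} - e^{sigma2}) / k` against
#' `e^{2s} - e^{s}` and solving the quadratic in `e^s` gives
#' `s = log[(1 + sqrt(1 + 4c)) / 2]` with `c` the matched variance. At
#' `k = 1` this collapses to `sigma2`; for `k >= 2` it satisfies
#' `sigma2 / k <= s <= sigma2`.
#'
#' @param sigma2 per-day error variance on the log scale.
#' @param k replicate count.
#' @return The equivalent single-error variance.
#' @export
sigma_reduced_log <- function(sigma2, k) {
  if (!is_count(k)) abort_mepsim("k must be a count >= 1", "spec")
  if (sigma2 < 0) abort_mepsim("sigma2 must be nonnegative", "spec")
  cc <- (exp(2 * sigma2) - exp(sigma2)) / k
  log((1 + sqrt(1 + 4 * cc)) / 2)
}

#' Monte-Carlo check of transform-then-average versus average-then-transform
#'
#' For a smooth transform `f` and iid errors `eps_j ~ N(0, sigma2)` around a
#' fixed location `Omega`, estimates by Monte Carlo the conditional variances
#' `lhs = var[f(Omega + mean(eps))]` (average first, then transform) and
#' `rhs = var[(1/k) sum f(Omega + eps_j)]` (transform each replicate, then
#' average). For convexly curved transforms the first is no larger; for an
#' affine transform the two coincide at `slope^2 * sigma2 / k`.
#'
#' @param f `"exp"`, `"cube"` (x^3) or `"affine"` (1 + 2x, slope 2).
#' @param sigma2 error variance.
#' @param k replicate count (>= 2 for the comparison to be informative).
#' @param mc_draws Monte-Carlo sample size.
#' @param seed integer seed.
#' @param Omega fixed conditioning value.
#' @return List with `lhs`, `rhs`, `gap = rhs - lhs` and `se_gap` (batch-mean
#'   standard error of the gap).
#' @export
lemma1_gap <- function(f = c("exp", "cube", "affine"), sigma2, k,
                       mc_draws = 1e6, seed = 1L, Omega = 0.5) {
  if (is.character(f)) {
    f <- match.arg(f)
    fn <- switch(f, exp = exp, cube = function(x) x^3,
                 affine = function(x) 1 + 2 * x)
  } else {
    abort_mepsim("unknown transform; use \"exp\", \"cube\" or \"affine\"",
                 "spec")
  }
  if (k < 2) abort_mepsim("k must be at least 2", "spec")
  n_batch <- 100L
  per <- floor(mc_draws / n_batch)
  with_seed(seed, {
    lhs_b <- rhs_b <- numeric(n_batch)
    for (b in seq_len(n_batch)) {
      eps <- matrix(stats::rnorm(per * k, 0, sqrt(sigma2)), per, k)
      a <- fn(Omega + rowMeans(eps))
      bb <- rowMeans(fn(Omega + eps))
      lhs_b[b] <- stats::var(a)
      rhs_b[b] <- stats::var(bb)
    }
    gap_b <- rhs_b - lhs_b
    list(lhs = mean(lhs_b), rhs = mean(rhs_b), gap = mean(gap_b),
         se_gap = stats::sd(gap_b) / sqrt(n_batch))
  })
}

#' Conditional error variance given an averaged surrogate
#'
#' Under the normal-normal classical model `X ~ N(mu, sigmaX2)`,
#' `Xbar* = X + Vbar` with `Vbar` the average of k errors of variance
#' `sigmaV2`, the residual error variance after observing the average is
#' `var(Vbar | Xbar*) = sigmaV2 * sigmaX2 / (sigmaV2 + k * sigmaX2)`. It
#' shrinks to zero as k grows: with enough replicates, prediction from the
#' error-prone average approaches prediction from the truth.
#'
#' @param sigmaV2 single-day error variance.
#' @param sigmaX2 variance of the true predictor.
#' @param k replicate count.
#' @return The conditional variance.
#' @export
conditional_error_variance <- function(sigmaV2, sigmaX2, k) {
  if (!is_count(k)) abort_mepsim("k must be a count >= 1", "spec")
  if (sigmaV2 < 0 || sigmaX2 < 0) abort_mepsim("variances must be nonnegative", "spec")
  if (sigmaV2 == 0 && sigmaX2 == 0) {
    abort_mepsim("at least one of sigmaV2, sigmaX2 must be positive", "spec")
  }
  sigmaV2 * sigmaX2 / (sigmaV2 + k * sigmaX2)
}

#' Fit the test-MSE scaling decomposition
#'
#' Decomposes observed test MSE over a grid of sample sizes and replicate
#' counts as `MSE(n, k) = sigmaY2 + C1 / k + C2 / n^(1 - delta)` by
#' nonnegative least squares.
#'
#' @param results data frame with columns `n`, `k` and `value` (test MSE);
#'   an `me_results` table is filtered to test-set MSE records first.
#' @param delta convergence-slack exponent (0 = parametric best case).
#' @return List of class `me_mse_scaling` with `sigmaY2_hat`, `C1_hat`,
#'   `C2_hat`, `delta`, `fitted` and `residuals`.
#' @export
fit_mse_scaling <- function(results, delta = 0) {
  df <- as.data.frame(results)
  if (all(c("split", "metric") %in% names(df))) {
    df <- df[df$split == "test" & df$metric == "mse", , drop = FALSE]
  }
  if (!all(c("n", "k", "value") %in% names(df))) {
    abort_mepsim("results must contain n, k and value columns", "spec")
  }
  if (nrow(unique(df[, c("n", "k")])) < 3) {
    abort_mepsim("need at least 3 distinct (n, k) pairs", "spec")
  }
  A <- cbind(1, 1 / df$k, 1 / df$n^(1 - delta))
  fit <- pracma::lsqnonneg(A, df$value)
  cf <- fit$x
  structure(
    list(sigmaY2_hat = cf[1], C1_hat = cf[2], C2_hat = cf[3], delta = delta,
         fitted = drop(A %*% cf), residuals = df$value - drop(A %*% cf)),
    class = "me_mse_scaling")
}

#' @export
print.me_mse_scaling <- function(x, ...) {
  cat(sprintf(
    "<me_mse_scaling> MSE(n, k) ~ %.4g + %.4g/k + %.4g/n^%.2g\n",
    x$sigmaY2_hat, x$C1_hat, x$C2_hat, 1 - x$delta))
  invisible(x)
}

#' Replicate-count versus sample-size trade-off table
#'
#' For a fixed measurement budget `total = n * k`, tabulates the conditional
#' error variance floor [conditional_error_variance()] across allocations.
#'
#' @param sigmaV2,sigmaX2 error and truth variances.
#' @param total total measurement budget.
#' @param k_grid replicate counts to tabulate (must divide `total`).
#' @return A tibble with columns `k`, `n` and `conditional_error_variance`.
#' @export
replicate_tradeoff <- function(sigmaV2, sigmaX2, total,
                               k_grid = c(1, 2, 4, 6, 8, 10)) {
  k_grid <- k_grid[total %% k_grid == 0]
  tibble::tibble(
    k = as.integer(k_grid),
    n = as.integer(total / k_grid),
    conditional_error_variance =
      vapply(k_grid, function(k) conditional_error_variance(sigmaV2, sigmaX2, k),
             numeric(1)))
}
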