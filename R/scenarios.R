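# Catalog of the four shipped simulation scenarios. All numeric values are
# the study conditions; overrides exist for sensitivity runs, not tuning.

sigma_u_12 <- function() matrix(c(20, 15.5, 15.5, 25.5), 2, 2)
sigma_eps_12 <- function() matrix(c(38, 20.5, 20.5, 34.5), 2, 2)

sigma_z_sim3 <- function() {
  matrix(c(1.28, 0.21, -0.07, 0.32,
           0.21, 1.98, 1.28, 0.34,
          -0.07, 1.28, 1.91, 1.22,
           0.32, 0.34, 1.22, 1.20), 4, 4, byrow = TRUE)
}

#' Construct a shipped simulation scenario
#'
#' Returns the full parameterisation of one of the five study scenarios:
#'
#' * `sim1`: two error-prone components, Box-Cox exponent 0.35, outcome
#'   linear in the ratio `X1/X2` (`alpha = (98.5, 4)`, `sigmaY2 = 1`);
#'   intercepts (36, 27.5), between-person covariance
#'   `[[20, 15.5], [15.5, 25.5]]`, within-person covariance
#'   `[[38, 20.5], [20.5, 34.5]]`. Defaults: n = 12000, days 2,4,6,8,10.
#' * `sim2`: identical to `sim1` but with exponent 0.5 (more skewness);
#'   run under a fixed total measurement budget.
#' * `sim3a` / `sim3b`: classical additive error on two components whose
#'   means are linear in four correlated covariates; outcome combines
#'   linear, product, log and ratio features plus `Z3`. Defaults:
#'   n = 40000, k = 2, 100 replications.
#' * `sim4`: three components with classical additive error and a binary
#'   outcome `P(Y=1|X) = expit(-1 + X2/30 * (I(X1>=100) - I(X3<=30)) +
#'   log(X3)/4)`. Defaults: n = 10000, k = 2, 100 replications.
#'
#' @param name one of `"sim1"`, `"sim2"`, `"sim3a"`, `"sim3b"`, `"sim4"`.
#' @param overrides named list of replacements applied to the error spec
#'   (`lambda`, `beta0`, `Sigma_u`, `Sigma_eps`, `observe`) or outcome spec
#'   (`alpha`, `sigmaY2`).
#' @return A list of class `me_scenario` with elements `name`, `error`,
#'   `outcome`, `z_gen` (covariate generator or `NULL`) and `defaults`
#'   (n_train, days/k grid, replications).
#' @export
make_scenario <- function(name = c("sim1", "sim2", "sim3a", "sim3b", "sim4"),
                          overrides = list()) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% c("sim1", "sim2", "sim3a", "sim3b", "sim4")) {
    abort_mepsim(sprintf("unknown scenario '%s'", paste(name, collapse = ",")),
                 "scenario")
  }
  sc <- switch(name,
    sim1 = ,
    sim2 = {
      lam <- if (name == "sim1") 0.35 else 0.5
      list(
        error = list(lambda = lam, beta0 = c(36, 27.5), betaZ = NULL,
                     Sigma_u = sigma_u_12(), Sigma_eps = sigma_eps_12(),
                     observe = "boxcox"),
        outcome = list(link = "identity", feature_map = "ratio",
                       alpha = c(98.5, 4.0), sigmaY2 = 1),
        z_gen = NULL,
        defaults = list(n_train = 12000L, days_grid = c(2L, 4L, 6L, 8L, 10L),
                        total_measurements = c(12000L, 60000L, 120000L),
                        replications = 5L))
    },
    sim3a = ,
    sim3b = {
      b0 <- if (name == "sim3a") 100 else 50
      alpha <- if (name == "sim3a") c(350, 2, -1, 3, 2, 1, -4, 1)
               else c(350, 1, -1, 50, 25, 25, -1, 1)
      Sz <- sigma_z_sim3()
      list(
        error = list(lambda = 1, beta0 = c(b0, b0),
                     betaZ = rbind(c(2, 0, -1, 0.5), c(0, 2, 1, -0.5)),
                     Sigma_u = sigma_u_12(), Sigma_eps = sigma_eps_12(),
                     observe = "boxcox"),
        outcome = list(link = "identity", feature_map = "sim3_nonlinear",
                       alpha = alpha, sigmaY2 = 1),
        z_gen = function(n, seed) with_seed(seed, rmvn(n, Sz)),
        defaults = list(n_train = 40000L, days_grid = 2L, replications = 100L))
    },
    sim4 = {
      list(
        error = list(lambda = 1, beta0 = c(100, 50, 30), betaZ = NULL,
                     Sigma_u = matrix(c(25, 20, 5,
                                        20, 20, 8,
                                         5,  8, 21), 3, 3, byrow = TRUE),
                     Sigma_eps = matrix(c(16, 32, 16,
                                          32, 80, 36,
                                          16, 36, 53), 3, 3, byrow = TRUE),
                     observe = "boxcox"),
        outcome = list(link = "expit", feature_map = "sim4_threshold",
                       alpha = c(-1, 1 / 30, 1 / 4), sigmaY2 = 0),
        z_gen = NULL,
        defaults = list(n_train = 10000L, days_grid = 2L, replications = 100L))
    })

  err_fields <- c("lambda", "beta0", "betaZ", "Sigma_u", "Sigma_eps", "observe")
  out_fields <- c("link", "feature_map", "alpha", "sigmaY2")
  for (key in names(overrides)) {
    if (key %in% err_fields) sc$error[[key]] <- overrides[[key]]
    else if (key %in% out_fields) sc$outcome[[key]] <- overrides[[key]]
    else abort_mepsim(sprintf("unknown override '%s'", key), "scenario")
  }
  structure(
    list(name = name,
         error = do.call(error_model_spec, sc$error),
         outcome = do.call(outcome_model_spec, sc$outcome),
         z_gen = sc$z_gen,
         defaults = sc$defaults),
    class = "me_scenario")
}

#' @export
print.me_scenario <- function(x, ...) {
  cat(sprintf("<me_scenario> %s: p = %d, q = %d, link = %s, h = %s\n",
              x$name, x$error$p, x$error$q, x$outcome$link,
              x$outcome$feature_map))
  invisible(x)
}
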