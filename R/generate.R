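# Replicate generator and the quadrature definition of true usual intake.

# mvrnorm that tolerates p = 1 and exactly singular covariances.
rmvn <- function(n, Sigma) {
  p <- nrow(Sigma)
  if (all(Sigma == 0)) return(matrix(0, n, p))
  matrix(MASS::mvrnorm(n, mu = rep(0, p), Sigma = Sigma, tol = 1e-8), n, p)
}

# Domain check for one replicate slab (n x p additive values): every component
# must map to a valid positive intake. Returns a logical vector (row valid).
valid_additive <- function(A, spec) {
  ok <- rep(TRUE, nrow(A))
  for (l in seq_len(spec$p)) {
    lam <- spec$lambda[l]
    if (abs(lam - 1) < 1e-12) {
      ok <- ok & (A[, l] > 0)        # classical scale: intakes are positive
    } else {
      ok <- ok & (lam * A[, l] + 1 > 0)
    }
  }
  ok
}

#' Draw replicate error-prone measurements
#'
#' Draws the person effects `u_i ~ N(0, Sigma_u)` once per person and the
#' day-level errors `eps_ij ~ N(0, Sigma_eps)` independently per replicate,
#' forms the additive-scale values `a_ilj = beta0_l + betaZ_l' Z_i + u_il +
#' eps_ilj` and observes either `X* = f^{-1}(a)` (inverse Box-Cox; identity
#' when `lambda = 1`) or `X* = a` (additive mode).
#'
#' Replicates whose additive value falls outside the domain of the inverse
#' transform (`lambda*a + 1 <= 0`), or that would produce a non-positive
#' intake on the classical scale, are rejected and redrawn; the rejection
#' rate is reported in the result and is negligible (~1e-6) at the shipped
#' scenario parameters.
#'
#' @param spec an [error_model_spec()].
#' @param n number of persons.
#' @param k number of replicates (days) per person.
#' @param Z optional `n x q` matrix of error-free covariates.
#' @param seed integer seed.
#' @return A list with `Xstar` (`n x p x k` observed array), `U` (`n x p`
#'   person effects), `additive` (`n x p x k` additive-scale array) and
#'   `rejection_rate`.
#' @export
draw_replicates <- function(spec, n, k, Z = NULL, seed = 1L) {
  stopifnot(inherits(spec, "me_error_spec"))
  if (!is_count(n) || !is_count(k)) abort_mepsim("n and k must be counts >= 1", "spec")
  p <- spec$p
  offset <- rep(spec$beta0, each = n)           # n x p baseline
  offset <- matrix(offset, n, p)
  if (spec$q > 0) {
    if (is.null(Z)) abort_mepsim("this spec needs an n x q covariate matrix Z", "spec")
    Z <- as.matrix(Z)
    if (nrow(Z) != n || ncol(Z) != spec$q || any(!is.finite(Z))) {
      abort_mepsim("Z must be a finite n x q matrix matching the spec", "spec")
    }
    offset <- offset + Z %*% t(spec$betaZ)
  }
  with_seed(seed, {
    U <- rmvn(n, spec$Sigma_u)
    A <- array(NA_real_, c(n, p, k))
    n_rejected <- 0L
    for (j in seq_len(k)) {
      eps <- rmvn(n, spec$Sigma_eps)
      slab <- offset + U + eps
      bad <- !valid_additive(slab, spec)
      iter <- 0L
      while (any(bad)) {
        iter <- iter + 1L
        if (iter > 100L) {
          abort_mepsim("replicate rejection did not terminate; check the spec scale",
                       "domain")
        }
        n_rejected <- n_rejected + sum(bad)
        eps_new <- rmvn(sum(bad), spec$Sigma_eps)
        slab[bad, ] <- offset[bad, , drop = FALSE] + U[bad, , drop = FALSE] + eps_new
        bad <- !valid_additive(slab, spec)
      }
      A[, , j] <- slab
    }
    Xstar <- A
    if (spec$observe == "boxcox") {
      for (l in seq_len(p)) {
        Xstar[, l, ] <- f_model_inv(A[, l, ], spec$lambda[l])
      }
    }
    rate <- n_rejected / (n * k + n_rejected)
    if (rate > 0.01) {
      warning(sprintf("draw_replicates: replicate rejection rate %.3g", rate))
    }
    list(Xstar = Xstar, U = U, additive = A, rejection_rate = rate)
  })
}

# Cached Gauss-Hermite rule (physicists' weighting exp(-t^2)).
gh_rule <- local({
  cache <- list()
  function(nodes) {
    key <- as.character(nodes)
    if (is.null(cache[[key]])) cache[[key]] <<- pracma::gaussHermite(nodes)
    cache[[key]]
  }
})

#' True usual intake
#'
#' Usual intake is defined as the expected observed intake for a person given
#' their covariates and between-person effect:
#' `X_l = E[ f^{-1}(beta0_l + betaZ_l' Z + u_l + eps_l) | Z, u_l ]`, the
#' expectation running over the day-level error `eps_l ~ N(0, Sigma_eps[l,l])`.
#' The expectation is computed by deterministic Gauss-Hermite quadrature
#' (41 nodes); nodes outside the domain of the inverse transform are dropped
#' and the weights renormalised, matching the rejection rule used by
#' [draw_replicates()]. For `lambda = 1` (identity) the mean-zero error
#' integrates out exactly and `X = beta0 + betaZ' Z + u`.
#'
#' @param spec an [error_model_spec()].
#' @param Z optional `n x q` covariate matrix (rows aligned with `U`).
#' @param U `n x p` matrix of person effects.
#' @param nodes number of quadrature nodes.
#' @return `n x p` matrix of usual intakes.
#' @export
true_usual_intake <- function(spec, Z = NULL, U, nodes = 41L) {
  stopifnot(inherits(spec, "me_error_spec"))
  U <- as.matrix(U)
  n <- nrow(U)
  mu <- matrix(rep(spec$beta0, each = n), n, spec$p) + U
  if (spec$q > 0) mu <- mu + as.matrix(Z) %*% t(spec$betaZ)
  X <- matrix(NA_real_, n, spec$p)
  gh <- gh_rule(nodes)
  for (l in seq_len(spec$p)) {
    lam <- spec$lambda[l]
    s <- sqrt(spec$Sigma_eps[l, l])
    if (abs(lam - 1) < 1e-12 || s == 0) {
      X[, l] <- if (abs(lam - 1) < 1e-12) mu[, l] else f_model_inv(mu[, l], lam)
      next
    }
    eps <- sqrt(2) * s * gh$x                   # quadrature abscissae for eps
    val <- outer(mu[, l], eps, "+")             # n x nodes additive values
    if (abs(lam) < 1e-12) {
      g <- exp(val)
      W <- matrix(gh$w, n, nodes, byrow = TRUE)
    } else {
      base <- lam * val + 1
      ok <- base > 0
      if (!all(ok)) base[!ok] <- 1              # masked out below
      g <- base^(1 / lam)
      W <- matrix(gh$w, n, nodes, byrow = TRUE) * ok
    }
    den <- rowSums(W)
    if (any(den == 0)) {
      abort_mepsim("quadrature domain empty for some person; check the spec", "domain")
    }
    X[, l] <- rowSums(W * g) / den
  }
  X
}

#' Simulate a complete replicate dataset
#'
#' Bundles covariates, replicate measurements, true usual intakes and
#' outcomes for `n` persons into one object. The retained truth `Xtrue` is
#' for diagnostics only; learners see only `Y`, `Xstar` and `Z`.
#'
#' @param scenario a scenario from [make_scenario()], or a list with elements
#'   `error` ([error_model_spec()]), `outcome` ([outcome_model_spec()]) and
#'   optionally `z_gen(n, seed)`.
#' @param n number of persons.
#' @param k replicates per person.
#' @param seed integer seed; covariates, person effects, errors and outcome
#'   noise all derive sub-seeds from it.
#' @return An object of class `me_dataset` with fields `Y`, `Xstar`
#'   (`n x p x k`), `Z`, `Xtrue`, `additive`, and the counts `n, p, q, k`.
#' @export
simulate_dataset <- function(scenario, n, k, seed = 1L) {
  es <- scenario$error; os <- scenario$outcome
  Z <- if (!is.null(scenario$z_gen)) scenario$z_gen(n, derive_seed(seed, "z")) else NULL
  reps <- draw_replicates(es, n, k, Z = Z, seed = derive_seed(seed, "x"))
  Xtrue <- true_usual_intake(es, Z = Z, U = reps$U)
  Y <- generate_outcome(os, Xtrue, Z, seed = derive_seed(seed, "y"))
  structure(
    list(Y = Y, Xstar = reps$Xstar, Z = Z, Xtrue = Xtrue,
         additive = reps$additive, rejection_rate = reps$rejection_rate,
         n = n, p = es$p, q = es$q, k = k),
    class = "me_dataset")
}

#' @export
print.me_dataset <- function(x, ...) {
  cat(sprintf("<me_dataset> n = %d, p = %d, q = %d, k = %d replicates\n",
              x$n, x$p, x$q, x$k))
  invisible(x)
}

#' Export a replicate dataset to CSV
#'
#' Columns are `y`, `x{l}_rep{j}` for each component and replicate, `z{m}`
#' and `xtrue{l}`.
#'
#' @param dataset an `me_dataset`.
#' @param path file path.
#' @return The path, invisibly.
#' @export
write_dataset_csv <- function(dataset, path) {
  df <- data.frame(y = dataset$Y)
  for (l in seq_len(dataset$p)) for (j in seq_len(dataset$k)) {
    df[[sprintf("x%d_rep%d", l, j)]] <- dataset$Xstar[, l, j]
  }
  if (dataset$q > 0) for (m in seq_len(dataset$q)) {
    df[[sprintf("z%d", m)]] <- dataset$Z[, m]
  }
  for (l in seq_len(dataset$p)) df[[sprintf("xtrue%d", l)]] <- dataset$Xtrue[, l]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
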