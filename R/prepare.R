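# Replicate-preparation strategies: how an n x p x k replicate array becomes
# the predictor matrix handed to a learner.

#' Prepare a predictor matrix from replicate measurements
#'
#' Three strategies are supported:
#'
#' * `"average"`: per-component arithmetic mean over the replicates used.
#' * `"concatenate"`: every replicate becomes its own column, component-major
#'   order (`x1_rep1, x1_rep2, ..., x2_rep1, ...`).
#' * `"transformed_average"`: a Box-Cox exponent is estimated per component
#'   from the pooled replicates ([estimate_lambda()]), each replicate is
#'   transformed, and the transformed values are averaged. By default the
#'   transformed-scale mean is fed to the learner directly; set
#'   `retransform = TRUE` to map it back through the inverse transform.
#'
#' Error-free covariates are appended unchanged under every strategy. When
#' preparing a test set, pass the `lambda_hat` estimated on the training set
#' so the transform is frozen.
#'
#' @param dataset an `me_dataset` from [simulate_dataset()].
#' @param strategy one of `"average"`, `"concatenate"`, `"transformed_average"`.
#' @param days_used number of replicates to use (the first `days_used`;
#'   replicates are exchangeable by construction). Defaults to all.
#' @param lambda_hat optional per-component exponent vector to reuse instead
#'   of estimating (train-set freeze).
#' @param retransform logical; back-transform the transformed-scale mean.
#' @param extra_log_of optional integer vector of component indices whose
#'   averaged value is additionally supplied log-transformed (appended as
#'   `log_x{l}` columns); used by the binary-outcome study.
#' @param replace_log logical; with `extra_log_of`, replace the raw averaged
#'   column by its log instead of appending.
#' @return An object of class `me_design`: list with the predictor matrix
#'   `M`, `strategy`, `lambda_hat` (transformed_average only), `k_used` and
#'   the column schema.
#' @export
prepare <- function(dataset, strategy = c("average", "concatenate",
                                          "transformed_average"),
                    days_used = dataset$k, lambda_hat = NULL,
                    retransform = FALSE, extra_log_of = integer(0),
                    replace_log = FALSE) {
  strategy <- match.arg(strategy)
  if (!is_count(days_used) || days_used > dataset$k) {
    abort_mepsim("days_used must be a count <= the dataset's replicate count",
                 "spec")
  }
  p <- dataset$p
  Xs <- dataset$Xstar[, , seq_len(days_used), drop = FALSE]
  avg_over <- function(arr) {       # n x p means over replicates
    out <- matrix(0, dataset$n, p)
    for (l in seq_len(p)) out[, l] <- rowMeans(arr[, l, , drop = FALSE])
    out
  }
  lam <- NULL
  if (strategy == "average") {
    M <- avg_over(Xs)
    colnames(M) <- sprintf("x%d_avg", seq_len(p))
  } else if (strategy == "concatenate") {
    M <- matrix(0, dataset$n, p * days_used)
    cn <- character(p * days_used)
    idx <- 0L
    for (l in seq_len(p)) for (j in seq_len(days_used)) {
      idx <- idx + 1L
      M[, idx] <- Xs[, l, j]
      cn[idx] <- sprintf("x%d_rep%d", l, j)
    }
    colnames(M) <- cn
  } else {
    lam <- lambda_hat
    if (is.null(lam)) {
      lam <- vapply(seq_len(p), function(l) estimate_lambda(Xs[, l, ]),
                    numeric(1))
    }
    lam <- rep_len(lam, p)
    Tarr <- Xs
    for (l in seq_len(p)) Tarr[, l, ] <- box_cox(Xs[, l, ], lam[l])
    M <- avg_over(Tarr)
    if (retransform) for (l in seq_len(p)) M[, l] <- box_cox_inv(M[, l], lam[l])
    colnames(M) <- sprintf("x%d_bcavg", seq_len(p))
  }
  if (length(extra_log_of) > 0) {
    if (strategy != "average") {
      abort_mepsim("extra_log_of is defined for the average strategy", "spec")
    }
    for (l in extra_log_of) {
      if (any(M[, l] <= 0)) {
        abort_mepsim("log of non-positive averaged component", "domain")
      }
      if (replace_log) {
        M[, l] <- log(M[, l])
        colnames(M)[l] <- sprintf("log_x%d_avg", l)
      } else {
        M <- cbind(M, log(M[, l]))
        colnames(M)[ncol(M)] <- sprintf("log_x%d_avg", l)
      }
    }
  }
  if (dataset$q > 0) {
    Z <- as.matrix(dataset$Z)
    colnames(Z) <- sprintf("z%d", seq_len(dataset$q))
    M <- cbind(M, Z)
  }
  structure(
    list(M = M, strategy = strategy, lambda_hat = lam, k_used = days_used,
         schema = colnames(M)),
    class = "me_design")
}

#' @export
print.me_design <- function(x, ...) {
  cat(sprintf("<me_design> %s, %d x %d [%s]\n", x$strategy, nrow(x$M),
              ncol(x$M), paste(x$schema, collapse = ", ")))
  invisible(x)
}

# Accept either an me_design or a bare matrix where a design is expected.
design_matrix <- function(design) {
  if (inherits(design, "me_design")) return(design$M)
  M <- as.matrix(design)
  if (is.null(colnames(M))) colnames(M) <- sprintf("v%d", seq_len(ncol(M)))
  M
}
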