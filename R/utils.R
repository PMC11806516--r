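# Shared helpers: structured errors, seed derivation, small checks.

abort_mepsim <- function(msg, type, ...) {
  stop(errorCondition(
    msg,
    ...,
    class = c(paste0("mepsim_error_", type), "mepsim_error", "error", "condition")
  ))
}

#' Derive a reproducible sub-stream seed
#'
#' All randomness in the package flows from a single root seed. Stages
#' (replications, train/test splits, learners) draw their own seeds through
#' this deterministic mixing function, so no stage perturbs another's stream.
#'
#' @param root integer root seed.
#' @param ... further integers (or strings, hashed by character codes)
#'   identifying the sub-stream.
#' @return An integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(root, ...) {
  parts <- list(...)
  h <- as.double(root) %% 2147483647
  for (p in parts) {
    if (is.character(p)) p <- sum(utf8ToInt(p) * seq_along(utf8ToInt(p)))
    for (v in as.double(p)) {
      h <- (h * 48271 + v + 11) %% 2147483647
    }
  }
  as.integer(h %% 2147483645 + 1)
}

# Run code under a seed without clobbering the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

check_psd <- function(S, name) {
  if (!is.matrix(S) || nrow(S) != ncol(S)) {
    abort_mepsim(sprintf("%s must be a square matrix", name), "spec")
  }
  if (max(abs(S - t(S))) > 1e-8 * max(1, max(abs(S)))) {
    abort_mepsim(sprintf("%s must be symmetric", name), "spec")
  }
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(1, max(abs(ev)))) {
    abort_mepsim(sprintf("%s is not positive semi-definite (min eigenvalue %.3g)",
                         name, min(ev)), "spec")
  }
  invisible(TRUE)
}

is_count <- function(x, min = 1L) {
  length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}

expit <- function(x) 1 / (1 + exp(-x))
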