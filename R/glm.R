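# Generalized linear learners and the shared evaluation contract.

#' Fit a (generalized) linear learner
#'
#' Identity link: ordinary least squares via [stats::lm.fit()]. Expit link:
#' logistic maximum likelihood via [stats::glm.fit()]. Deterministic given
#' its inputs. Rank deficiency is a structured error naming the collinear
#' columns.
#'
#' @param design an `me_design` (or bare predictor matrix).
#' @param y outcome vector (0/1 for the expit link).
#' @param link `"identity"` or `"expit"`.
#' @return A fitted model of class `me_model` (family `linear`/`logistic`).
#' @export
fit_glm <- function(design, y, link = c("identity", "expit")) {
  link <- match.arg(link)
  M <- design_matrix(design)
  if (nrow(M) != length(y)) abort_mepsim("design and y lengths differ", "spec")
  if (nrow(M) <= ncol(M)) abort_mepsim("need n > number of predictors", "spec")
  X <- cbind(`(Intercept)` = 1, M)
  if (link == "identity") {
    fit <- stats::lm.fit(X, y)
    if (fit$rank < ncol(X)) {
      bad <- colnames(X)[is.na(fit$coefficients)]
      abort_mepsim(sprintf("rank-deficient design; collinear column(s): %s",
                           paste(bad, collapse = ", ")), "rank")
    }
    coefs <- fit$coefficients
    family <- "linear"
  } else {
    fit <- suppressWarnings(
      stats::glm.fit(X, y, family = stats::binomial()))
    if (any(is.na(fit$coefficients))) {
      bad <- colnames(X)[is.na(fit$coefficients)]
      abort_mepsim(sprintf("rank-deficient design; collinear column(s): %s",
                           paste(bad, collapse = ", ")), "rank")
    }
    coefs <- fit$coefficients
    family <- "logistic"
  }
  structure(
    list(family = family, coefficients = coefs, link = link,
         input_schema = colnames(M),
         training_log = tibble::tibble(epoch = integer(0),
                                       train_loss = numeric(0),
                                       val_loss = numeric(0), lr = numeric(0))),
    class = c(paste0("me_", family), "me_model"))
}

check_schema <- function(model, M) {
  if (!identical(colnames(M), model$input_schema)) {
    abort_mepsim(sprintf(
      "input schema mismatch: model expects [%s], got [%s]",
      paste(model$input_schema, collapse = ", "),
      paste(colnames(M), collapse = ", ")), "schema")
  }
}

#' Predict from a fitted learner
#'
#' @param object an `me_model`.
#' @param design an `me_design` (or matrix) with the same column schema the
#'   model was trained on.
#' @param ... unused.
#' @return Numeric predictions; probabilities in (0, 1) for the expit link.
#' @export
predict.me_model <- function(object, design, ...) {
  M <- design_matrix(design)
  check_schema(object, M)
  eta <- drop(cbind(1, M) %*% object$coefficients)
  if (object$link == "expit") expit(eta) else eta
}

#' Evaluate predictions
#'
#' `"mse"` is the mean squared difference; `"accuracy"` is the fraction of
#' correct classifications at threshold 0.5, predictions exactly at 0.5
#' classified positive.
#'
#' @param yhat predictions.
#' @param y observed outcomes.
#' @param metric `"mse"` or `"accuracy"`.
#' @return A scalar.
#' @export
evaluate <- function(yhat, y, metric = c("mse", "accuracy")) {
  metric <- match.arg(metric)
  if (length(yhat) == 0 || length(yhat) != length(y)) {
    abort_mepsim("yhat and y must be equal-length, non-empty", "spec")
  }
  if (metric == "mse") mean((y - yhat)^2) else mean((yhat >= 0.5) == (y == 1))
}

#' Majority-class baseline accuracy
#'
#' The accuracy on `y_eval` of a constant model predicting the majority
#' class of `y_train` (ties broken towards the positive class).
#'
#' @param y_train training outcomes (0/1).
#' @param y_eval outcomes to score against.
#' @return A scalar accuracy.
#' @export
constant_model_accuracy <- function(y_train, y_eval) {
  maj <- as.numeric(mean(y_train == 1) >= 0.5)
  mean(y_eval == maj)
}
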