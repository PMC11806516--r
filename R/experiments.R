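# Orchestration of the four simulation studies: grids over replicate days,
# sample sizes, preparation strategies and learners, emitting long-form
# metric records.

#' Build an experiment plan
#'
#' Fills scenario-specific defaults and applies a desk-scale factor. The
#' full-scale designs are: study 1, n = 12000 with 2/4/6/8/10 replicate
#' days; study 2, total measurement budgets 12000/60000/120000 split evenly
#' across the days grid (n = total / days); study 3, n = 40000 and k = 2
#' with 100 replications; study 4, n = 10000 and k = 2 with 100
#' replications. `scale_factor` shrinks the sample sizes, the epoch budget
#' and the replication count proportionally for desk runs (replications
#' floored at 3).
#'
#' @param scenario scenario name (see [make_scenario()]).
#' @param n_train,n_test training/testing sample sizes (test defaults to
#'   train, matching the study design).
#' @param days_grid replicate-day grid.
#' @param total_measurements fixed measurement budgets (study 2 mode:
#'   n = total / days for each days value).
#' @param preparations subset of `c("average", "concatenate",
#'   "transformed_average")`.
#' @param learners subset of `c("linear", "mlp")` (study 4 uses
#'   `c("logistic", "mlp", "mlp_early")`).
#' @param replications number of Monte-Carlo replications.
#' @param scale_factor proportion applied to sample sizes, epochs and
#'   replications.
#' @param mlp named list of [mlp_config()] overrides applied to every
#'   network in the plan.
#' @param seed root seed; every replication and model derives sub-seeds.
#' @param verbose emit one progress line per cell to stderr.
#' @return A list of class `me_plan`.
#' @export
experiment_plan <- function(scenario, n_train = NULL, n_test = NULL,
                            days_grid = NULL, total_measurements = NULL,
                            preparations = c("average", "concatenate",
                                             "transformed_average"),
                            learners = NULL, replications = NULL,
                            scale_factor = 1, mlp = list(), seed = 1L,
                            verbose = FALSE) {
  sc <- make_scenario(scenario)
  d <- sc$defaults
  if (is.null(n_train)) n_train <- d$n_train
  if (is.null(days_grid)) days_grid <- d$days_grid
  if (is.null(replications)) replications <- d$replications
  if (is.null(learners)) {
    learners <- switch(scenario,
                       sim4 = c("logistic", "mlp", "mlp_early"),
                       sim2 = "mlp",
                       c("linear", "mlp"))
  }
  if (scenario == "sim2" && is.null(total_measurements)) {
    total_measurements <- d$total_measurements
  }
  if (any(days_grid < 1)) abort_mepsim("days_grid entries must be >= 1", "plan")
  if (scale_factor <= 0 || scale_factor > 1) {
    abort_mepsim("scale_factor must be in (0, 1]", "plan")
  }
  if (scale_factor < 1) {
    n_train <- max(500L, as.integer(round(n_train * scale_factor)))
    if (!is.null(total_measurements)) {
      total_measurements <- pmax(2000L, as.integer(round(
        total_measurements * scale_factor)))
      # keep every budget divisible by every days value
      lcm_days <- Reduce(pracma::Lcm, days_grid)
      total_measurements <- as.integer(
        pmax(lcm_days, round(total_measurements / lcm_days) * lcm_days))
    }
    replications <- max(3L, as.integer(ceiling(replications * scale_factor)))
    if (is.null(mlp$max_epochs)) {
      mlp$max_epochs <- max(120L, as.integer(round(1500 * scale_factor)))
    }
    if (is.null(mlp$lr_drop_every)) {
      mlp$lr_drop_every <- max(30L, as.integer(round(300 * scale_factor)))
    }
  }
  if (is.null(n_test)) n_test <- n_train
  structure(
    list(scenario = scenario, n_train = as.integer(n_train),
         n_test = as.integer(n_test), days_grid = as.integer(days_grid),
         total_measurements = total_measurements,
         preparations = preparations, learners = learners,
         replications = as.integer(replications),
         scale_factor = scale_factor, mlp = mlp, seed = as.integer(seed),
         verbose = isTRUE(verbose)),
    class = "me_plan")
}

#' @export
print.me_plan <- function(x, ...) {
  cat(sprintf(
    "<me_plan> %s: n_train = %d, days = {%s}, reps = %d, learners = {%s}\n",
    x$scenario, x$n_train, paste(x$days_grid, collapse = ","),
    x$replications, paste(x$learners, collapse = ",")))
  invisible(x)
}

plan_mlp_config <- function(plan, output_link, seed, extra = list()) {
  args <- utils::modifyList(plan$mlp, extra)
  args$output_link <- output_link
  args$seed <- seed
  do.call(mlp_config, args)
}

say <- function(plan, fmt, ...) {
  if (plan$verbose) message(sprintf(fmt, ...))
}

result_row <- function(scenario, replication, n, k, preparation, learner,
                       split, metric, value) {
  tibble::tibble(scenario = scenario, replication = as.integer(replication),
                 n = as.integer(n), k = as.integer(k),
                 preparation = preparation, learner = learner, split = split,
                 metric = metric, value = as.numeric(value))
}

empty_results <- function() {
  result_row(character(0), integer(0), integer(0), integer(0), character(0),
             character(0), character(0), character(0), numeric(0))
}

# Fit one learner on prepared train/test designs and return the two records.
fit_and_score <- function(y_tr, y_te, des_tr, des_te, learner, link, metric,
                          mlp_cfg = NULL) {
  model <- switch(learner,
    linear = fit_glm(des_tr, y_tr, link = "identity"),
    logistic = fit_glm(des_tr, y_tr, link = "expit"),
    fit_mlp(des_tr, y_tr, config = mlp_cfg))
  list(train = evaluate(predict(model, des_tr), y_tr, metric),
       test = evaluate(predict(model, des_te), y_te, metric))
}

#' Run simulation study 1: preparation strategies and replicate days
#'
#' For every replication and days value, simulates paired training/testing
#' datasets under the Box-Cox error model, builds the three preparation
#' strategies (the transform exponent estimated on training data and frozen
#' for the test set), fits the linear and network learners on identical
#' data, and records train/test MSE.
#'
#' @param plan an [experiment_plan()] for scenario `sim1`.
#' @return A long-form tibble of metric records.
#' @export
run_sim1 <- function(plan) {
  stopifnot(plan$scenario %in% c("sim1", "sim2"))
  sc <- make_scenario(plan$scenario)
  out <- list()
  for (r in seq_len(plan$replications)) {
    for (d in plan$days_grid) {
      n <- plan$n_train
      cell_seed <- derive_seed(plan$seed, plan$scenario, r, d)
      ds_tr <- simulate_dataset(sc, n, d, seed = derive_seed(cell_seed, "train"))
      ds_te <- simulate_dataset(sc, plan$n_test, d,
                                seed = derive_seed(cell_seed, "test"))
      for (prep in plan$preparations) {
        des_tr <- prepare(ds_tr, prep)
        des_te <- prepare(ds_te, prep, lambda_hat = des_tr$lambda_hat)
        for (learner in plan$learners) {
          cfg <- if (learner == "mlp") {
            plan_mlp_config(plan, "identity",
                            derive_seed(cell_seed, prep, learner))
          }
          sc_res <- fit_and_score(ds_tr$Y, ds_te$Y, des_tr, des_te, learner,
                                  "identity", "mse", cfg)
          say(plan, "%s rep %d days %d %s/%s: train %.3f test %.3f",
              plan$scenario, r, d, prep, learner, sc_res$train, sc_res$test)
          out[[length(out) + 1L]] <- rbind(
            result_row(plan$scenario, r, n, d, prep, learner, "train", "mse",
                       sc_res$train),
            result_row(plan$scenario, r, n, d, prep, learner, "test", "mse",
                       sc_res$test))
        }
      }
    }
  }
  do.call(rbind, c(out, list(empty_results())))
}

#' Run simulation study 2: sample size versus replicate count
#'
#' Keeps the total number of measurements fixed and splits it across the
#' days grid (`n = total / days`), so more replicate days mean fewer
#' persons. Uses the skewer Box-Cox exponent 0.5.
#'
#' @param plan an [experiment_plan()] for scenario `sim2` with
#'   `total_measurements` set.
#' @return A long-form tibble of metric records.
#' @export
run_sim2 <- function(plan) {
  stopifnot(plan$scenario == "sim2")
  if (is.null(plan$total_measurements)) {
    abort_mepsim("sim2 requires total_measurements", "plan")
  }
  out <- list()
  for (total in plan$total_measurements) {
    if (any(total %% plan$days_grid != 0)) {
      abort_mepsim(sprintf(
        "total_measurements %d not divisible by days value(s) %s", total,
        paste(plan$days_grid[total %% plan$days_grid != 0], collapse = ",")),
        "plan")
    }
    for (d in plan$days_grid) {
      sub <- plan
      sub$n_train <- as.integer(total / d)
      sub$n_test <- as.integer(total / d)
      sub$days_grid <- d
      sub$seed <- derive_seed(plan$seed, "total", total)
      res <- run_sim1(sub)
      res$n_total <- as.integer(total)
      out[[length(out) + 1L]] <- res
    }
  }
  do.call(rbind, out)
}

sim3_designs <- function(ds, arm, spec_out, lambda_unused = NULL) {
  Zn <- as.matrix(ds$Z)
  colnames(Zn) <- sprintf("z%d", seq_len(ncol(Zn)))
  M <- switch(arm,
    error_free = {
      Xt <- ds$Xtrue; colnames(Xt) <- sprintf("x%d", seq_len(ncol(Xt)))
      cbind(Xt, Zn)
    },
    oracle = {
      H <- outcome_features(spec_out, ds$Xtrue, ds$Z)
      colnames(H) <- c("x1", "x2", "x1x2", "logx1", "logx2", "x1_over_x2", "z3")
      H
    },
    errorprone_linear = return(prepare(ds, "average")),
    errorprone_log = return(prepare(ds, "average", extra_log_of = c(1L, 2L))))
  structure(list(M = M, strategy = arm, lambda_hat = NULL, k_used = ds$k,
                 schema = colnames(M)), class = "me_design")
}

#' Run simulation study 3: nonlinear outcomes
#'
#' Compares arms on the same simulated data: `error_free` (true usual
#' intakes entered linearly with the covariates), `oracle` (the correctly
#' specified feature set on true intakes; the theoretical-floor reference),
#' `errorprone_linear` (2-day averages entered linearly) and
#' `errorprone_log` (averages plus their logs). Each arm is fit with the
#' learners in the plan and scored by train/test MSE.
#'
#' @param plan an [experiment_plan()] for scenario `sim3a` or `sim3b`.
#' @param arms subset of the four arms.
#' @return A long-form tibble of metric records (`preparation` holds the arm).
#' @export
run_sim3 <- function(plan, arms = c("error_free", "oracle",
                                    "errorprone_linear", "errorprone_log")) {
  stopifnot(plan$scenario %in% c("sim3a", "sim3b"))
  sc <- make_scenario(plan$scenario)
  k <- plan$days_grid[1]
  out <- list()
  for (r in seq_len(plan$replications)) {
    cell_seed <- derive_seed(plan$seed, plan$scenario, r)
    ds_tr <- simulate_dataset(sc, plan$n_train, k,
                              seed = derive_seed(cell_seed, "train"))
    ds_te <- simulate_dataset(sc, plan$n_test, k,
                              seed = derive_seed(cell_seed, "test"))
    for (arm in arms) {
      des_tr <- sim3_designs(ds_tr, arm, sc$outcome)
      des_te <- sim3_designs(ds_te, arm, sc$outcome)
      for (learner in plan$learners) {
        cfg <- if (learner == "mlp") {
          plan_mlp_config(plan, "identity", derive_seed(cell_seed, arm, learner))
        }
        sc_res <- fit_and_score(ds_tr$Y, ds_te$Y, des_tr, des_te, learner,
                                "identity", "mse", cfg)
        say(plan, "%s rep %d %s/%s: train %.3f test %.3f", plan$scenario, r,
            arm, learner, sc_res$train, sc_res$test)
        out[[length(out) + 1L]] <- rbind(
          result_row(plan$scenario, r, plan$n_train, k, arm, learner, "train",
                     "mse", sc_res$train),
          result_row(plan$scenario, r, plan$n_train, k, arm, learner, "test",
                     "mse", sc_res$test))
      }
    }
  }
  do.call(rbind, c(out, list(empty_results())))
}

#' Run simulation study 4: binary prediction
#'
#' Binary outcome driven by thresholds and a log term. Learners: logistic
#' regression, the default network (batch 1000, early-stopping checks every
#' 50 epochs), and an aggressively early-stopped network (batch 250, checks
#' every 10 epochs). Each runs on the plain 2-day averages and on the
#' variant where the third component's average is log-transformed. Records
#' train/test accuracy plus the majority-class constant baseline.
#'
#' @param plan an [experiment_plan()] for scenario `sim4`.
#' @return A long-form tibble of metric records.
#' @export
run_sim4 <- function(plan) {
  stopifnot(plan$scenario == "sim4")
  sc <- make_scenario("sim4")
  k <- plan$days_grid[1]
  preps <- list(average = integer(0), average_log3 = 3L)
  out <- list()
  for (r in seq_len(plan$replications)) {
    cell_seed <- derive_seed(plan$seed, "sim4", r)
    ds_tr <- simulate_dataset(sc, plan$n_train, k,
                              seed = derive_seed(cell_seed, "train"))
    ds_te <- simulate_dataset(sc, plan$n_test, k,
                              seed = derive_seed(cell_seed, "test"))
    out[[length(out) + 1L]] <- rbind(
      result_row("sim4", r, plan$n_train, k, "none", "constant", "train",
                 "accuracy", constant_model_accuracy(ds_tr$Y, ds_tr$Y)),
      result_row("sim4", r, plan$n_train, k, "none", "constant", "test",
                 "accuracy", constant_model_accuracy(ds_tr$Y, ds_te$Y)))
    for (prep in names(preps)) {
      des_tr <- prepare(ds_tr, "average", extra_log_of = preps[[prep]],
                        replace_log = TRUE)
      des_te <- prepare(ds_te, "average", extra_log_of = preps[[prep]],
                        replace_log = TRUE)
      for (learner in plan$learners) {
        cfg <- if (learner == "mlp") {
          plan_mlp_config(plan, "expit", derive_seed(cell_seed, prep, learner))
        } else if (learner == "mlp_early") {
          plan_mlp_config(plan, "expit", derive_seed(cell_seed, prep, learner),
                          extra = list(batch_size = 250L,
                                       early_stop_every = 10L))
        }
        actual <- if (learner == "mlp_early") "mlp" else learner
        sc_res <- fit_and_score(ds_tr$Y, ds_te$Y, des_tr, des_te, actual,
                                "expit", "accuracy", cfg)
        say(plan, "sim4 rep %d %s/%s: train %.3f test %.3f", r, prep, learner,
            sc_res$train, sc_res$test)
        out[[length(out) + 1L]] <- rbind(
          result_row("sim4", r, plan$n_train, k, prep, learner, "train",
                     "accuracy", sc_res$train),
          result_row("sim4", r, plan$n_train, k, prep, learner, "test",
                     "accuracy", sc_res$test))
      }
    }
  }
  do.call(rbind, c(out, list(empty_results())))
}

#' Run the experiment a plan describes
#'
#' Dispatches to the scenario-specific runner.
#'
#' @param plan an [experiment_plan()].
#' @param ... passed through to the runner.
#' @return A long-form tibble of metric records.
#' @export
run_experiment <- function(plan, ...) {
  switch(plan$scenario,
    sim1 = run_sim1(plan),
    sim2 = run_sim2(plan),
    sim3a = ,
    sim3b = run_sim3(plan, ...),
    sim4 = run_sim4(plan))
}

#' Aggregate long-form results
#'
#' Mean and standard deviation of the metric over replications within every
#' (scenario, n, k, preparation, learner, split, metric) cell.
#'
#' @param results a long-form results tibble.
#' @return A tibble with `mean_value`, `sd_value` and `n_reps` per cell.
#' @export
summarize_results <- function(results) {
  df <- as.data.frame(results)
  keys <- intersect(c("scenario", "n", "k", "n_total", "preparation",
                      "learner", "split", "metric"), names(df))
  grp <- interaction(df[keys], drop = TRUE, lex.order = TRUE)
  first <- !duplicated(grp)
  out <- df[first, keys, drop = FALSE]
  out$mean_value <- as.numeric(tapply(df$value, grp, mean)[as.character(grp[first])])
  out$sd_value <- as.numeric(tapply(df$value, grp, stats::sd)[as.character(grp[first])])
  out$n_reps <- as.integer(tapply(df$value, grp, length)[as.character(grp[first])])
  out <- out[do.call(order, out[keys]), , drop = FALSE]
  rownames(out) <- NULL
  tibble::as_tibble(out)
}
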