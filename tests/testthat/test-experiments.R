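small_sim1_plan <- function(seed = 33, ...) {
  experiment_plan("sim1", n_train = 600, days_grid = 2L, replications = 2L,
                  learners = "linear", seed = seed, ...)
}

test_that("plans fill scenario defaults and validate their grids", {
  p1 <- experiment_plan("sim1")
  expect_equal(p1$n_train, 12000L)
  expect_equal(p1$days_grid, c(2L, 4L, 6L, 8L, 10L))
  expect_equal(p1$n_test, p1$n_train)
  p2 <- experiment_plan("sim2")
  expect_equal(p2$total_measurements, c(12000L, 60000L, 120000L))
  expect_equal(p2$learners, "mlp")
  p4 <- experiment_plan("sim4")
  expect_equal(p4$learners, c("logistic", "mlp", "mlp_early"))
  expect_equal(p4$n_train, 10000L)
  expect_equal(p4$replications, 100L)
  expect_mepsim_error(experiment_plan("sim1", days_grid = c(0, 2)), "plan")
})

test_that("desk scaling shrinks sizes, budgets, epochs and replications together", {
  p <- experiment_plan("sim1", scale_factor = 1 / 6)
  expect_equal(p$n_train, 2000L)
  expect_equal(p$replications, 3L)
  expect_equal(p$mlp$max_epochs, 250L)
  expect_equal(p$mlp$lr_drop_every, 50L)
  p2 <- experiment_plan("sim2", scale_factor = 0.2)
  expect_true(all(p2$total_measurements %% Reduce(pracma::Lcm, p2$days_grid) == 0))
  expect_equal(max(p2$total_measurements), 24000L)
})

test_that("a zero-replication plan yields an empty result without error", {
  plan <- experiment_plan("sim1", replications = 0L, learners = "linear")
  res <- run_sim1(plan)
  expect_s3_class(res, "tbl_df")
  expect_equal(nrow(res), 0)
  expect_named(res, c("scenario", "replication", "n", "k", "preparation",
                      "learner", "split", "metric", "value"))
})

test_that("fixed-budget mode enforces divisibility and splits the sample", {
  plan <- experiment_plan("sim2", n_train = 1, days_grid = c(2L, 5L),
                          total_measurements = 1200L, replications = 1L,
                          learners = "linear")
  res <- run_sim2(plan)
  expect_setequal(unique(res$n), c(600L, 240L))
  expect_equal(unique(res$n_total), 1200L)
  bad <- experiment_plan("sim2", days_grid = c(2L, 7L),
                         total_measurements = 1200L, replications = 1L,
                         learners = "linear")
  expect_mepsim_error(run_sim2(bad), "plan")
})

test_that("experiment records are reproducible bit-for-bit from the plan", {
  res1 <- run_sim1(small_sim1_plan())
  res2 <- run_sim1(small_sim1_plan())
  expect_identical(res1, res2)
  res3 <- run_sim1(small_sim1_plan(seed = 34))
  expect_false(identical(res1$value, res3$value))
  # one record per grid cell and split
  expect_equal(nrow(res1), 2 * 3 * 1 * 1 * 2)  # reps x preps x days x learners x splits
})

test_that("training loss does not exceed testing loss on average", {
  # the optimism gap scales with d/n, so use a small sample and enough
  # replications for the averages to separate
  plan <- experiment_plan("sim1", n_train = 150, days_grid = 2L,
                          replications = 12L, learners = "linear", seed = 55)
  res <- run_sim1(plan)
  tr <- mean(res$value[res$split == "train"])
  te <- mean(res$value[res$split == "test"])
  expect_lt(tr, te)
})

test_that("aggregation matches a brute-force recomputation", {
  res <- run_sim1(small_sim1_plan(seed = 77))
  s <- summarize_results(res)
  cell <- res[res$preparation == "average" & res$split == "test", ]
  expect_equal(
    s$mean_value[s$preparation == "average" & s$split == "test"],
    mean(cell$value))
  expect_equal(
    s$sd_value[s$preparation == "average" & s$split == "test"],
    sd(cell$value))
  expect_equal(unique(s$n_reps), 2L)
})

test_that("study-3 arms expose truth, oracle and error-prone designs", {
  plan <- experiment_plan("sim3a", n_train = 1500, replications = 1L,
                          learners = "linear", seed = 9)
  res <- run_sim3(plan)
  s <- summarize_results(res)
  mse <- function(arm) s$mean_value[s$preparation == arm & s$split == "test"]
  # correctly specified oracle reaches the residual floor; the linear-terms
  # error-free arm is blocked by the product nonlinearity; error-prone arms
  # are blocked further by the measurement error
  expect_lt(mse("oracle"), 1.5)
  expect_gt(mse("error_free"), 10 * mse("oracle"))
  expect_gt(mse("errorprone_linear"), mse("error_free"))
})

test_that("study-4 records cover constant baseline, learners and preparations", {
  plan <- experiment_plan("sim4", n_train = 900, replications = 1L,
                          learners = "logistic", seed = 14)
  res <- run_sim4(plan)
  expect_setequal(unique(res$learner), c("constant", "logistic"))
  expect_setequal(unique(res$preparation), c("none", "average", "average_log3"))
  expect_true(all(res$metric == "accuracy"))
  acc <- summarize_results(res)
  base <- acc$mean_value[acc$learner == "constant" & acc$split == "test"]
  fit <- acc$mean_value[acc$learner == "logistic" & acc$split == "test"]
  expect_true(all(fit > base))
})

test_that("run_experiment dispatches on the plan scenario", {
  res <- run_experiment(small_sim1_plan(seed = 3))
  expect_equal(unique(res$scenario), "sim1")
  plan3 <- experiment_plan("sim3b", n_train = 800, replications = 1L,
                           learners = "linear", seed = 4)
  res3 <- run_experiment(plan3, arms = "oracle")
  expect_equal(unique(res3$preparation), "oracle")
})
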