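test_that("degenerate zero-variance spec reproduces the intercepts exactly", {
  spec <- error_model_spec(lambda = 1, beta0 = c(36, 27.5),
                           Sigma_u = matrix(0, 2, 2),
                           Sigma_eps = matrix(0, 2, 2))
  reps <- draw_replicates(spec, n = 5, k = 3, seed = 1)
  expect_true(all(reps$Xstar[, 1, ] == 36))
  expect_true(all(reps$Xstar[, 2, ] == 27.5))
  expect_true(all(reps$U == 0))
})

test_that("additive-scale moments follow the law of total covariance", {
  spec <- error_model_spec(lambda = 0.35, beta0 = c(36, 27.5),
                           Sigma_u = matrix(c(20, 15.5, 15.5, 25.5), 2),
                           Sigma_eps = matrix(c(38, 20.5, 20.5, 34.5), 2),
                           observe = "additive")
  n <- 30000
  reps <- draw_replicates(spec, n = n, k = 2, seed = 9)
  # across persons: Sigma_u + Sigma_eps
  S <- cov(reps$Xstar[, , 1])
  expect_equal(S, matrix(c(58, 36, 36, 60), 2), tolerance = 0.05,
               ignore_attr = TRUE)
  # within person, across replicates: the shared person effect Sigma_u
  expect_equal(cov(reps$Xstar[, 1, 1], reps$Xstar[, 1, 2]), 20,
               tolerance = 0.06)
  expect_equal(cov(reps$Xstar[, 2, 1], reps$Xstar[, 2, 2]), 25.5,
               tolerance = 0.06)
})

test_that("spec validation rejects broken covariance inputs", {
  bad <- matrix(c(1, 2, 2, 1), 2)   # eigenvalues 3, -1
  expect_mepsim_error(
    error_model_spec(lambda = 1, beta0 = c(0, 0), Sigma_u = bad,
                     Sigma_eps = diag(2)), "spec")
  expect_mepsim_error(
    error_model_spec(lambda = 1, beta0 = c(0, 0), Sigma_u = diag(2),
                     Sigma_eps = matrix(c(1, 0.5, 0.4, 1), 2)), "spec")
})

test_that("true usual intake matches closed forms and a Monte-Carlo oracle", {
  # identity transform: the mean-zero day error integrates out exactly
  spec1 <- error_model_spec(lambda = 1, beta0 = c(10, 20),
                            Sigma_u = diag(2), Sigma_eps = 4 * diag(2))
  U <- matrix(c(1, -2, 0.5, 0), 2, 2)
  expect_equal(true_usual_intake(spec1, U = U),
               matrix(c(11, 8, 20.5, 20), 2, 2))
  # log transform: lognormal mean exp(mu + sigma^2/2)
  spec0 <- error_model_spec(lambda = 0, beta0 = 1.5, Sigma_u = diag(1),
                            Sigma_eps = matrix(0.49))
  u <- matrix(c(-0.3, 0, 0.4), 3, 1)
  expect_equal(true_usual_intake(spec0, U = u),
               matrix(exp(1.5 + u + 0.49 / 2), 3, 1), tolerance = 1e-8)
  # Box-Cox 0.35 at the shipped scale: quadrature vs brute-force MC
  sc <- make_scenario("sim1")
  u_row <- matrix(c(2.5, -1.0), 1, 2)
  xq <- true_usual_intake(sc$error, U = u_row)
  set.seed(77)
  for (l in 1:2) {
    eps <- rnorm(1e6, 0, sqrt(sc$error$Sigma_eps[l, l]))
    add <- sc$error$beta0[l] + u_row[1, l] + eps
    add <- add[0.35 * add + 1 > 0]
    x_mc <- mean((0.35 * add + 1)^(1 / 0.35))
    expect_equal(xq[1, l], x_mc, tolerance = 1e-3)
  }
})

test_that("same-seed datasets are bit-identical and share truth across replicates", {
  ds1 <- sim1_dataset(n = 200, k = 3, seed = 5)
  ds2 <- sim1_dataset(n = 200, k = 3, seed = 5)
  expect_identical(ds1, ds2)
  ds3 <- sim1_dataset(n = 200, k = 3, seed = 6)
  expect_false(identical(ds1$Y, ds3$Y))
})

test_that("with identity transform the replicate mean converges to the truth", {
  spec <- error_model_spec(lambda = 1, beta0 = c(100, 50),
                           Sigma_u = matrix(c(25, 20, 20, 20), 2),
                           Sigma_eps = matrix(c(16, 2, 2, 8), 2))
  reps <- draw_replicates(spec, n = 300, k = 400, seed = 3)
  truth <- true_usual_intake(spec, U = reps$U)
  for (l in 1:2) {
    person_mean <- rowMeans(reps$Xstar[, l, ])
    expect_lt(max(abs(person_mean - truth[, l])), 1.5)
    expect_equal(mean(person_mean - truth[, l]), 0, tolerance = 0.05)
  }
})

test_that("outcome generator honours link, features and determinism", {
  # ratio feature map with the shipped coefficients, noiseless
  os <- outcome_model_spec("identity", "ratio", alpha = c(98.5, 4), sigmaY2 = 0)
  X <- matrix(c(7, 3, 7, 3), 2, 2)   # ratio 1 for both persons
  expect_equal(generate_outcome(os, X, seed = 1), c(102.5, 102.5))
  # threshold map: indicator bracket cancels at X = (100, 30, 30)
  os4 <- outcome_model_spec("expit", "sim4_threshold",
                            alpha = c(-1, 1 / 30, 1 / 4))
  p <- outcome_mean(os4, matrix(c(100, 30, 30), 1, 3))
  expect_equal(p, 1 / (1 + exp(-(-1 + log(30) / 4))))
  # null expit model is a fair coin
  os_null <- outcome_model_spec("expit", "linear", alpha = c(0, 0))
  y <- generate_outcome(os_null, matrix(rnorm(20000), ncol = 1), seed = 2)
  expect_equal(mean(y), 0.5, tolerance = 0.02)
  # noiseless identity outcome is a pure function of X
  expect_identical(generate_outcome(os, X, seed = 10),
                   generate_outcome(os, X, seed = 99))
  # structured error for log of a non-positive component
  expect_mepsim_error(
    outcome_mean(os4, matrix(c(100, 30, -1), 1, 3)), "domain")
})

test_that("scenario catalog carries the printed parameterizations", {
  s1 <- make_scenario("sim1")
  expect_equal(s1$error$Sigma_eps[1, 1], 38)
  expect_equal(s1$error$lambda, c(0.35, 0.35))
  expect_equal(s1$outcome$alpha, c(98.5, 4))
  s2 <- make_scenario("sim2")
  expect_equal(s2$error$lambda, c(0.5, 0.5))
  s2$error$lambda <- s1$error$lambda
  expect_equal(unclass(s2$error), unclass(s1$error))
  s4 <- make_scenario("sim4")
  expect_equal(s4$outcome$alpha, c(-1, 1 / 30, 1 / 4))
  expect_equal(s4$error$beta0, c(100, 50, 30))
  s3 <- make_scenario("sim3a")
  expect_equal(dim(s3$error$betaZ), c(2, 4))
  expect_mepsim_error(make_scenario("sim99"), "scenario")
  # overrides reach into the right spec
  s1b <- make_scenario("sim1", overrides = list(sigmaY2 = 0, lambda = 0.5))
  expect_equal(s1b$outcome$sigmaY2, 0)
  expect_equal(s1b$error$lambda, c(0.5, 0.5))
  expect_mepsim_error(make_scenario("sim1", overrides = list(bogus = 1)),
                      "scenario")
})

test_that("dataset CSV export lays out replicates, covariates and truth", {
  ds <- simulate_dataset(make_scenario("sim3a"), 30, 2, seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset_csv(ds, path)
  df <- read.csv(path)
  expect_identical(names(df),
                   c("y", "x1_rep1", "x1_rep2", "x2_rep1", "x2_rep2",
                     paste0("z", 1:4), "xtrue1", "xtrue2"))
  expect_equal(df$x2_rep2, ds$Xstar[, 2, 2])
  expect_equal(df$xtrue1, ds$Xtrue[, 1])
})
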