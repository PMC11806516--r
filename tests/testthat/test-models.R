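test_that("linear and logistic fits satisfy their closed-form contracts", {
  set.seed(2)
  M <- cbind(a = rnorm(50), b = rnorm(50))
  y <- 3 + 2 * M[, 1] - M[, 2]
  fit <- fit_glm(M, y)
  expect_equal(evaluate(predict(fit, M), y), 0, tolerance = 1e-20)
  # intercept-only fit returns the mean
  one <- matrix(rnorm(40), 40, 1, dimnames = list(NULL, "x"))
  fit0 <- fit_glm(one, rep(4, 40))
  expect_equal(unname(predict(fit0, one)), rep(4, 40))
  # symmetric no-signal logistic data: near-zero coefficients
  Ms <- matrix(c(-1, 1, -1, 1), 4, 1, dimnames = list(NULL, "x"))
  ys <- c(0, 1, 1, 0)
  fl <- fit_glm(Ms, ys, link = "expit")
  expect_equal(unname(fl$coefficients), c(0, 0), tolerance = 1e-6)
  # rank deficiency is a structured error naming the collinear column
  Mr <- cbind(u = rnorm(30), v = 0)
  Mr <- cbind(Mr, w = Mr[, 1] * 2)
  err <- tryCatch(fit_glm(Mr, rnorm(30)), condition = identity)
  expect_s3_class(err, "mepsim_error_rank")
  expect_match(conditionMessage(err), "w|v")
})

test_that("prediction enforces the input schema and is row-equivariant", {
  ds <- sim1_dataset(n = 100)
  des <- prepare(ds, "average")
  fit <- fit_glm(des, ds$Y)
  wrong <- des$M
  colnames(wrong) <- c("x2_avg", "x1_avg")
  expect_mepsim_error(predict(fit, wrong), "schema")
  perm <- sample(nrow(des$M))
  expect_equal(predict(fit, des$M[perm, ]), predict(fit, des$M)[perm])
})

test_that("evaluation metrics: arithmetic, perfection and the tie rule", {
  expect_equal(evaluate(c(1, 2), c(1, 4)), 2)
  y <- c(0, 1, 1, 0)
  expect_equal(evaluate(y, y, "mse"), 0)
  expect_equal(evaluate(y, y, "accuracy"), 1)
  # exact 0.5 classifies positive, so balanced outcomes score 0.5
  expect_equal(evaluate(rep(0.5, 4), y, "accuracy"), 0.5)
  expect_mepsim_error(evaluate(numeric(0), numeric(0)), "spec")
  expect_equal(constant_model_accuracy(c(1, 1, 0), c(1, 0, 1, 0)), 0.5)
  expect_equal(constant_model_accuracy(c(0, 0, 1), c(0, 0, 1, 0)), 0.75)
})

test_that("backpropagation gradients match finite differences", {
  set.seed(99)
  n <- 12; d <- 3
  X <- matrix(rnorm(n * d), n, d)
  y <- rnorm(n)
  for (link in c("identity", "expit")) {
    if (link == "expit") y <- rbinom(n, 1, 0.5)
    for (bn in c(TRUE, FALSE)) {
      cfg <- mlp_config(layer_sizes = c(4L, 3L), output_link = link,
                        dropout = 0, batch_norm = bn, batch_size = n,
                        val_fraction = 0.2, seed = 1)
      pars <- with_seed(5, mepsim:::mlp_init_params(d, cfg, y = y))
      state <- list(bn_mean = lapply(cfg$layer_sizes, function(h) rep(0, h)),
                    bn_var = lapply(cfg$layer_sizes, function(h) rep(1, h)))
      loss_at <- function(p) {
        fwd <- mepsim:::mlp_forward(p, X, cfg, state, training = TRUE)
        mepsim:::mlp_loss(fwd$z, y, link)
      }
      fwd <- mepsim:::mlp_forward(pars, X, cfg, state, training = TRUE)
      g <- mepsim:::mlp_backward(pars, fwd, X, y, cfg)
      h <- 1e-6
      for (grp in names(g)) {
        for (i in seq_along(g[[grp]])) {
          idx <- seq_len(min(5, length(g[[grp]][[i]])))
          for (j in idx) {
            pp <- pars; pp[[grp]][[i]][j] <- pp[[grp]][[i]][j] + h
            pm <- pars; pm[[grp]][[i]][j] <- pm[[grp]][[i]][j] - h
            num <- (loss_at(pp) - loss_at(pm)) / (2 * h)
            expect_lt(abs(g[[grp]][[i]][j] - num), 1e-5 * max(1, abs(num)))
          }
        }
      }
    }
  }
})

test_that("a zero-hidden-layer network trained to convergence matches OLS", {
  ds <- sim1_dataset(n = 400, k = 2, seed = 12)
  des <- prepare(ds, "average")
  cfg <- mlp_config(layer_sizes = integer(0), dropout = 0, batch_norm = FALSE,
                    batch_size = 400L, learning_rate = 0.05, weight_decay = 0,
                    lr_drop_every = 1200L, max_epochs = 3000L,
                    early_stop_every = 3000L, val_fraction = 0.1, seed = 3)
  m0 <- fit_mlp(des, ds$Y, cfg)
  ols <- fit_glm(des$M[m0$train_idx, , drop = FALSE], ds$Y[m0$train_idx])
  rel <- sqrt(mean((predict(m0, des) - predict(ols, des$M))^2)) / sd(ds$Y)
  expect_lt(rel, 0.01)
})

test_that("network training contracts: constant target, determinism, logging", {
  ds <- sim1_dataset(n = 300, k = 2, seed = 8)
  des <- prepare(ds, "average")
  # constant target is learned to near-zero loss
  mc <- fit_mlp(des, rep(2.5, 300), quick_mlp())
  expect_equal(unname(predict(mc, des)), rep(2.5, 300), tolerance = 0.05)
  expect_lt(evaluate(predict(mc, des), rep(2.5, 300)), 1e-3)
  # bit-identical training under the same seed
  m1 <- fit_mlp(des, ds$Y, quick_mlp())
  m2 <- fit_mlp(des, ds$Y, quick_mlp())
  expect_identical(m1$training_log, m2$training_log)
  expect_identical(m1$parameters, m2$parameters)
  m3 <- fit_mlp(des, ds$Y, quick_mlp(seed = 8L))
  expect_false(identical(m1$training_log, m3$training_log))
  # log columns and the step learning-rate schedule
  expect_named(m1$training_log, c("epoch", "train_loss", "val_loss", "lr"))
  expect_equal(m1$training_log$lr,
               0.05 / 10^floor((m1$training_log$epoch - 1) / 40))
  # probabilities stay in (0, 1) under the expit link
  yb <- as.numeric(ds$Y > median(ds$Y))
  mb <- fit_mlp(des, yb, quick_mlp(output_link = "expit"))
  pb <- predict(mb, des)
  expect_true(all(pb > 0 & pb < 1))
})

test_that("expected test error sits above the residual-variance floor", {
  # error-free truth with the correct feature map: MSE can approach sigmaY2
  # but not undercut it; with error-prone inputs the floor strictly exceeds it
  sc <- make_scenario("sim1")
  ds_tr <- simulate_dataset(sc, 3000, 2, seed = 31)
  ds_te <- simulate_dataset(sc, 3000, 2, seed = 32)
  ratio_tr <- cbind(r = ds_tr$Xtrue[, 1] / ds_tr$Xtrue[, 2])
  ratio_te <- cbind(r = ds_te$Xtrue[, 1] / ds_te$Xtrue[, 2])
  oracle <- fit_glm(ratio_tr, ds_tr$Y)
  mse_oracle <- evaluate(predict(oracle, ratio_te), ds_te$Y)
  expect_gt(mse_oracle, 0.9 * 1)
  expect_lt(mse_oracle, 1.2)
  des_tr <- prepare(ds_tr, "average")
  des_te <- prepare(ds_te, "average")
  noisy <- fit_glm(des_tr, ds_tr$Y)
  expect_gt(evaluate(predict(noisy, des_te), ds_te$Y), 1)
})
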