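# Shared fixtures: all built in code at test time.

sim1_dataset <- function(n = 500, k = 2, seed = 42) {
  simulate_dataset(make_scenario("sim1"), n, k, seed = seed)
}

# A small, fast network configuration for contract tests (not the study
# protocol; those run in the scaled experiment tests).
quick_mlp <- function(seed = 7L, ...) {
  mlp_config(layer_sizes = c(16L, 16L), batch_size = 200L,
             learning_rate = 0.05, max_epochs = 80L, lr_drop_every = 40L,
             early_stop_every = 20L, val_fraction = 0.15, seed = seed, ...)
}

expect_mepsim_error <- function(expr, type) {
  expect_error(expr, class = paste0("mepsim_error_", type))
}
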