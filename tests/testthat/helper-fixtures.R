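# Shared fixtures, built in code at test time.

test_protocol <- function() default_ivim_protocol()

# A small seeded Rician IVIM dataset: 3^4 grid, `reps` instantiations.
tiny_dataset <- function(sigma = 0.1, reps = 2, seed = 101, n_levels = 3) {
  build_dataset(make_parameter_grid(n_levels = n_levels), test_protocol(),
                sigma = sigma, reps_per_combo = reps, seed = seed)
}

# Fraction of voxels with every parameter within `tol` relative error.
recovered_fraction <- function(estimates, truth, tol = 0.05) {
  est <- as.matrix(as.data.frame(estimates)[, c("Dt", "Dp", "f", "S0")])
  tr <- as.matrix(as.data.frame(truth)[, c("Dt", "Dp", "f", "S0")])
  mean(apply(abs(est - tr) / tr, 1, max) < tol)
}

# Cache for expensive shared computations (network bias studies): computed
# once per test run, reused across test_that() blocks.
.study_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .study_cache))
    assign(key, force(expr), envir = .study_cache)
  get(key, envir = .study_cache)
}

# Scaled-down replication of the synthetic training study at one SNR:
# 10-level grid, 50k training voxels, best-of-3 x 60-epoch NLR common
# initialisation, then <= 100 post-initialisation epochs per requested loss.
# Returns per-loss predictions plus the test truth.
run_bias_study <- function(snr, losses, seed = 1) {
  protocol <- test_protocol()
  study <- simulate_ivim_study(snr, protocol, n_levels = 10, reps_train = 5,
                               reps_test = 5, n_val = 1000, seed = seed)
  sigma <- study$noise$sigma
  cfg <- network_config(protocol$n_measurements)
  tci <- training_config("NLR", sigma = sigma, max_epochs = 60,
                         patience = 60, init_repetitions = 3, seed = seed)
  init <- common_initialisation(cfg, protocol, study$train, study$val, tci)
  preds <- lapply(losses, function(loss) {
    tc <- training_config(loss, sigma = sigma, max_epochs = 100,
                          patience = 100, seed = seed)
    net <- train_network(init, study$train, study$val, tc)
    predict(net, study$test)
  })
  names(preds) <- losses
  list(preds = preds, truth = study$test$truth, noise = study$noise)
}
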