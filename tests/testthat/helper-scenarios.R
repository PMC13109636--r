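# Shared fixtures: calibrated scenarios are expensive, so they are memoized
# per (dgp, level, mdag) for the whole test run.  Calibration samples are
# smaller than the study default; intercept accuracy at n_cal = 3e4 is well
# within the tolerances asserted here.

.scenario_cache <- new.env(parent = emptyenv())

cached_scenario <- function(dgp = 1, level = 1, mdag = "A", n = 2000,
                            master_seed = 101, n_cal = 30000, ...) {
  key <- paste(dgp, level, mdag, n, master_seed, n_cal, sep = "|")
  if (is.null(.scenario_cache[[key]])) {
    cfg <- scenario_config(dgp, level, mdag, n = n, master_seed = master_seed,
                           n_cal = n_cal, ...)
    .scenario_cache[[key]] <- calibrate_scenario(cfg)
  }
  .scenario_cache[[key]]
}

# small randomized-trial-style dataset with a known additive effect
toy_trial <- function(n = 2000, ate = 0.5, seed = 1) {
  set.seed(seed)
  W <- data.frame(W1 = rbinom(n, 1, 0.5), W2 = rnorm(n))
  A <- rbinom(n, 1, 0.5)
  Y <- 1 + ate * A + 0.4 * W$W1 + 0.3 * W$W2 + rnorm(n)
  cbind(W, A = A, Y = Y)
}

fast_sl <- function(seed = 11) sl_spec(c("glm", "mean"), folds = 5, seed = seed)
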