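#' Relative bias in percent
#'
#' `100 * (mean(estimates) - truth) / truth`.
#'
#' @param estimates vector of point estimates over replicates.
#' @param truth true parameter value.
#' @return relative bias in percent.
#' @export
relative_bias <- function(estimates, truth) {
  100 * (mean(estimates) - truth) / truth
}

#' Root mean squared error
#'
#' `sqrt(mean((estimates - truth)^2))`.
#'
#' @inheritParams relative_bias
#' @return RMSE on the estimate's scale.
#' @export
rmse <- function(estimates, truth) sqrt(mean((estimates - truth)^2))

#' Empirical confidence-interval coverage in percent
#'
#' @param ci_lows,ci_highs interval endpoints over replicates.
#' @param truth true parameter value.
#' @return percentage of intervals containing the truth.
#' @export
coverage <- function(ci_lows, ci_highs, truth) {
  100 * mean(ci_lows <= truth & truth <= ci_highs)
}

#' Monte Carlo uncertainty band for an estimated coverage rate
#'
#' `nominal +/- 1.96 * sqrt(nominal * (1 - nominal) / nsim)`, expressed in
#' percent and rounded to one decimal; with 1000 replicates a nominal 95%
#' rate is expected between 93.6% and 96.4%.
#'
#' @param nsim number of simulation replicates.
#' @param nominal nominal coverage probability (e.g. 0.95).
#' @return numeric vector `c(low_pct, high_pct)`.
#' @export
mc_coverage_interval <- function(nsim, nominal = 0.95) {
  half <- 1.96 * sqrt(nominal * (1 - nominal) / nsim)
  round(100 * c(nominal - half, nominal + half), 1)
}

#' Estimate the ATE from observed data with one missing-data strategy
#'
#' Dispatcher over the eight strategies: `"cc"` (complete cases + TMLE),
#' `"ext"` (extended TMLE with an outcome-missingness model), `"ext_mcmi"`
#' (missing covariate missing indicator + extended TMLE), and the MI engines
#' `"mi_pmm"`, `"mi_int"`, `"mi_cart"`, `"mi_rf"`, `"mi_norm"` (joint-normal
#' EMB), each pooled by Rubin's rules with TMLE as the analysis model.
#'
#' @param obs ObservedData from [apply_missingness()].
#' @param method strategy label.
#' @param slspec an [sl_spec()].
#' @param imspec an [imputation_spec()] (MI methods; its `method` field is
#'   overridden by the strategy label).
#' @return an `ate_estimate`.
#' @export
estimate_ate <- function(obs, method, slspec = sl_spec(),
                         imspec = imputation_spec("pmm")) {
  switch(method,
    cc = {
      res <- tmle_ate(prepare_cc(obs), slspec)
      res$method <- "cc"
      res
    },
    ext = {
      res <- tmle_ext(prepare_ext(obs), slspec)
      res$method <- "ext"
      res
    },
    ext_mcmi = {
      d <- prepare_ext_mcmi(obs)
      cov <- setdiff(names(d), c("A", "Y", "B", "M_Y"))
      res <- tmle_ext(d, slspec, covariates = cov)
      res$method <- "ext_mcmi"
      res
    },
    mi_pmm = mi_analyze(obs, replace_method(imspec, "pmm"), slspec),
    mi_int = mi_analyze(obs, replace_method(imspec, "pmm_int"), slspec),
    mi_cart = mi_analyze(obs, replace_method(imspec, "cart"), slspec),
    mi_rf = mi_analyze(obs, replace_method(imspec, "rf"), slspec),
    mi_norm = mi_analyze(obs, replace_method(imspec, "jm_norm"), slspec),
    stop("unknown method: ", method))
}

replace_method <- function(imspec, method) {
  imspec$method <- method
  imspec
}

#' All strategy labels understood by [estimate_ate()]
#' @return character vector.
#' @export
study_methods <- function() {
  c("cc", "ext", "ext_mcmi", "mi_pmm", "mi_int", "mi_cart", "mi_rf", "mi_norm")
}

#' Run a simulation study grid
#'
#' For each scenario and replicate: generate complete data, impose the
#' scenario's m-DAG missingness with frozen calibrated intercepts, apply each
#' strategy, estimate, and summarize per (DGP, level, m-DAG, method) cell
#' with relative bias, RMSE and coverage plus their Monte Carlo standard
#' errors.  Replicates use independent derived seed streams, so results are
#' identical regardless of execution order; failures are logged, excluded and
#' counted.
#'
#' @param configs list of [scenario_config()] objects.
#' @param methods character vector of strategy labels.
#' @param slspec an [sl_spec()].
#' @param imspec an [imputation_spec()].
#' @param n_reps replicates per scenario (default: each config's `n_reps`).
#' @param keep_estimates also return the per-replicate estimate table.
#' @return data.frame of class `simulation_summary` (attribute `estimates`
#'   when requested).
#' @export
run_study <- function(configs, methods = c("cc", "ext"), slspec = sl_spec(),
                      imspec = imputation_spec("pmm"), n_reps = NULL,
                      keep_estimates = FALSE) {
  if (inherits(configs, "scenario_config")) configs <- list(configs)
  rows <- list()
  est_rows <- list()
  for (cfg in configs) {
    if (is.null(cfg$calibration)) cfg <- calibrate_scenario(cfg)
    reps <- if (is.null(n_reps)) cfg$n_reps else n_reps
    res <- list()
    for (m in methods) res[[m]] <- list(ate = c(), lo = c(), hi = c(), fail = 0L)
    for (r in seq_len(reps)) {
      obsd <- generate_observed_data(cfg, r)
      for (m in methods) {
        fit <- tryCatch(estimate_ate(obsd, m, slspec, imspec),
                        error = function(e) e)
        if (inherits(fit, "error")) {
          res[[m]]$fail <- res[[m]]$fail + 1L
        } else {
          res[[m]]$ate <- c(res[[m]]$ate, fit$ate)
          res[[m]]$lo <- c(res[[m]]$lo, fit$ci[1])
          res[[m]]$hi <- c(res[[m]]$hi, fit$ci[2])
          if (keep_estimates)
            est_rows[[length(est_rows) + 1]] <- data.frame(
              dgp_id = cfg$dgp_id, level = cfg$positivity_level,
              mdag = cfg$mdag, method = m, rep = r, ate = fit$ate,
              se = fit$se, ci_low = fit$ci[1], ci_high = fit$ci[2])
        }
      }
    }
    for (m in methods) {
      x <- res[[m]]
      ns <- length(x$ate)
      rows[[length(rows) + 1]] <- data.frame(
        dgp_id = cfg$dgp_id, level = cfg$positivity_level, mdag = cfg$mdag,
        method = m, nsim = ns, n_failed = x$fail,
        flagged = x$fail > 0.02 * reps,
        relative_bias_pct = relative_bias(x$ate, cfg$true_ate),
        rmse = rmse(x$ate, cfg$true_ate),
        coverage_pct = coverage(x$lo, x$hi, cfg$true_ate),
        bias_mc_se_pct = 100 * sd(x$ate) / sqrt(ns) / cfg$true_ate,
        coverage_mc_se_pct = 100 * sqrt(mean(x$lo <= cfg$true_ate &
                                               cfg$true_ate <= x$hi) *
          (1 - mean(x$lo <= cfg$true_ate & cfg$true_ate <= x$hi)) / ns))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("simulation_summary", class(out))
  if (keep_estimates) attr(out, "estimates") <- do.call(rbind, est_rows)
  out
}
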