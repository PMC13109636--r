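#' Sample mixed marginals coupled through a Gaussian copula
#'
#' Draws latent multivariate normal vectors with correlation `corr`, maps them
#' to uniforms, and applies each column's inverse CDF.  Marginal parameters may
#' be vectors (one value per row), which is how the confounders' regressions on
#' the auxiliary variable B enter.
#'
#' @param marginal_specs named list; each element is a list with `type` in
#'   `"bernoulli"` (`p`), `"normal"` (`mean`, `sd`), `"categorical"` (`prob`,
#'   an n x K matrix of row probabilities), or `"gamma"` (`shape`, `rate`).
#' @param corr symmetric positive-definite correlation matrix, one row per spec.
#' @param n number of rows.
#' @param seed optional integer seed.
#' @return data.frame with one column per marginal spec.
#' @export
sample_gaussian_copula <- function(marginal_specs, corr, n, seed = NULL) {
  k <- length(marginal_specs)
  stopifnot(is.matrix(corr), nrow(corr) == k, ncol(corr) == k)
  if (!isTRUE(all.equal(corr, t(corr))) || any(abs(diag(corr) - 1) > 1e-12))
    stop("corr must be symmetric with unit diagonal")
  ch <- tryCatch(chol(corr), error = function(e)
    stop("corr is not positive definite"))
  with_seed(seed, {
    z <- matrix(rnorm(n * k), n, k) %*% ch
    u <- pnorm(z)
    out <- vector("list", k)
    for (j in seq_len(k)) {
      sp <- marginal_specs[[j]]
      out[[j]] <- switch(sp$type,
        bernoulli = as.numeric(u[, j] > 1 - sp$p), # inverse CDF: 1 on the upper tail
        normal = qnorm(u[, j], mean = sp$mean, sd = sp$sd),
        categorical = {
          pr <- sp$prob
          cp <- pr[, 1]
          cat <- rep(1L, n)
          for (kk in 2:ncol(pr)) {
            cat <- cat + as.integer(u[, j] > cp)
            cp <- cp + pr[, kk]
          }
          cat
        },
        gamma = qgamma(u[, j], shape = sp$shape, rate = sp$rate),
        stop("unknown marginal type: ", sp$type))
    }
    names(out) <- names(marginal_specs)
    as.data.frame(out)
  })
}

#' Per-row softmax category probabilities
#'
#' @param b numeric vector (the auxiliary variable B).
#' @param gamma0,gamma1 length-4 coefficient vectors; category k has linear
#'   predictor `gamma0[k] + gamma1[k] * b`.
#' @return n x 4 matrix of probabilities summing to 1 per row.
#' @export
softmax_probs <- function(b, gamma0, gamma1) {
  stopifnot(length(gamma0) == 4, length(gamma1) == 4)
  lp <- outer(b, gamma1) + matrix(gamma0, length(b), 4, byrow = TRUE)
  lp <- lp - apply(lp, 1, max)
  e <- exp(lp)
  e / rowSums(e)
}

#' Draw the four-category confounder from its softmax model
#'
#' @inheritParams softmax_probs
#' @param seed optional integer seed.
#' @return integer vector of categories in 1..4.
#' @export
sample_categorical_softmax <- function(b, gamma0, gamma1, seed = NULL) {
  pr <- softmax_probs(b, gamma0, gamma1)
  with_seed(seed, {
    u <- runif(length(b))
    cp <- pr[, 1]
    cat <- rep(1L, length(b))
    for (k in 2:4) {
      cat <- cat + as.integer(u > cp)
      cp <- cp + pr[, k]
    }
    cat
  })
}

#' Draw the gamma confounder whose shape and rate depend on truncated B
#'
#' `tB = clamp(b, -0.99, 0.99)` guarantees positive shape `xi0 + xi1*tB` and
#' rate `tau0 + tau1*tB` provided `xi0 > 0.99*|xi1|` and `tau0 > 0.99*|tau1|`.
#'
#' @param b numeric vector.
#' @param xi0,xi1 shape coefficients.
#' @param tau0,tau1 rate coefficients.
#' @param seed optional integer seed.
#' @return positive numeric vector.
#' @export
sample_gamma_confounder <- function(b, xi0, xi1, tau0, tau1, seed = NULL) {
  if (xi0 - 0.99 * abs(xi1) <= 0 || tau0 - 0.99 * abs(tau1) <= 0)
    stop("gamma parameters not positive over the truncation range [-0.99, 0.99]")
  tb <- pmin(pmax(b, -0.99), 0.99)
  with_seed(seed, rgamma(length(b), shape = xi0 + xi1 * tb, rate = tau0 + tau1 * tb))
}

#' Inflate the exposure-model interaction coefficients for a positivity level
#'
#' Level 1 leaves the base coefficients untouched; each higher level doubles
#' the interaction coefficients relative to the previous level (so level 3 is
#' four times the base).  Main effects are never touched; the exposure
#' intercept must be recalibrated afterwards to keep the 15% prevalence.
#'
#' @param eta named exposure-coefficient vector.
#' @param level positivity level 1-3.
#' @param interactions names of the interaction entries (default: every name
#'   containing `":"`).
#' @return the modified coefficient vector.
#' @export
inflate_positivity <- function(eta, level, interactions = grep(":", names(eta), value = TRUE)) {
  if (!level %in% 1:3) stop("positivity level must be 1, 2 or 3")
  eta[interactions] <- eta[interactions] * 2^(level - 1)
  eta
}

#' Solve a logistic-model intercept for a target marginal probability
#'
#' Finds `c` with `mean(plogis(c + lp)) = target_prob` by monotone
#' root-finding, to within 1e-6 on the achieved mean.
#'
#' @param target_prob target marginal probability in (0, 1).
#' @param linear_predictor_samples linear predictors excluding the intercept.
#' @return the intercept.
#' @export
calibrate_intercept <- function(target_prob, linear_predictor_samples) {
  if (target_prob <= 0 || target_prob >= 1) stop("target_prob must be in (0,1)")
  lp <- linear_predictor_samples
  stopifnot(length(lp) > 0)
  f <- function(c) mean(plogis(c + lp)) - target_prob
  uniroot(f, lower = -50, upper = 50, extendInt = "yes", tol = 1e-10)$root
}

# ---- design matrices ---------------------------------------------------------

# binary view of W3 used inside interaction terms (categorical DGPs split 1-2
# vs 3-4; binary DGPs use W3 itself)
w3_binary <- function(data, dgp_id) {
  if (dgp_id >= 4) as.numeric(data$W3 >= 3) else data$W3
}

#' Exposure-model design matrix (columns named like the coefficient map)
#' @param data CompleteData-style data.frame.
#' @param dgp_id integer 1-5.
#' @return numeric matrix without intercept column.
#' @export
exposure_design <- function(data, dgp_id) {
  w3b <- w3_binary(data, dgp_id)
  cols <- list(W1 = data$W1, W2 = data$W2)
  if (dgp_id >= 4) {
    cols$W3_2 <- as.numeric(data$W3 == 2)
    cols$W3_3 <- as.numeric(data$W3 == 3)
    cols$W3_4 <- as.numeric(data$W3 == 4)
  } else cols$W3 <- data$W3
  cols$W4 <- data$W4
  cols$W5 <- data$W5
  if (dgp_id == 5) cols$W6 <- data$W6
  cols$B <- data$B
  cols[["W1:W3"]] <- data$W1 * w3b
  cols[["W1:W4"]] <- data$W1 * data$W4
  cols[["W1:W5"]] <- data$W1 * data$W5
  cols[["W3:W4"]] <- w3b * data$W4
  cols[["W3:W5"]] <- w3b * data$W5
  cols[["W4:W5"]] <- data$W4 * data$W5
  do.call(cbind, cols)
}

#' Outcome-model design matrix (columns named like the coefficient map)
#' @inheritParams exposure_design
#' @param A exposure vector to place in the design (defaults to `data$A`).
#' @return numeric matrix without intercept column.
#' @export
outcome_design <- function(data, dgp_id, A = data$A) {
  w3b <- w3_binary(data, dgp_id)
  cols <- list(A = A, W1 = data$W1, W2 = data$W2)
  if (dgp_id >= 4) {
    cols$W3_2 <- as.numeric(data$W3 == 2)
    cols$W3_3 <- as.numeric(data$W3 == 3)
    cols$W3_4 <- as.numeric(data$W3 == 4)
  } else cols$W3 <- data$W3
  cols$W4 <- data$W4
  cols$W5 <- data$W5
  if (dgp_id == 5) cols$W6 <- data$W6
  cols[["W1:W3"]] <- data$W1 * w3b
  cols[["W1:W4"]] <- data$W1 * data$W4
  cols[["W1:W5"]] <- data$W1 * data$W5
  cols[["W3:W4"]] <- w3b * data$W4
  cols[["W3:W5"]] <- w3b * data$W5
  cols[["W4:W5"]] <- data$W4 * data$W5
  cols[["W1:W3:W4"]] <- data$W1 * w3b * data$W4
  cols[["W1:W3:W5"]] <- data$W1 * w3b * data$W5
  cols[["W1:W4:W5"]] <- data$W1 * data$W4 * data$W5
  cols[["W3:W4:W5"]] <- w3b * data$W4 * data$W5
  cols[["W1:W3:W4:W5"]] <- data$W1 * w3b * data$W4 * data$W5
  do.call(cbind, cols)
}

# ---- confounder + auxiliary sampling ----------------------------------------

sample_confounders <- function(config, n, seed = NULL) {
  co <- config$coeff
  dgp <- config$dgp_id
  with_seed(seed, {
    b <- rnorm(n)
    specs <- list(W1 = list(type = "bernoulli", p = plogis(co$alpha0)),
                  W2 = list(type = "bernoulli", p = plogis(co$beta[1] + co$beta[2] * b)))
    specs$W3 <- if (dgp >= 4)
      list(type = "categorical", prob = softmax_probs(b, co$gamma0, co$gamma1))
    else list(type = "bernoulli", p = plogis(co$gamma[1] + co$gamma[2] * b))
    specs$W4 <- if (dgp >= 2)
      list(type = "normal", mean = co$delta[1] + co$delta[2] * b, sd = 1)
    else list(type = "bernoulli", p = plogis(co$delta[1] + co$delta[2] * b))
    specs$W5 <- if (dgp >= 2)
      list(type = "normal", mean = co$zeta0, sd = 2)
    else list(type = "bernoulli", p = plogis(co$zeta0))
    if (dgp == 5) {
      if (co$gshape[1] - 0.99 * abs(co$gshape[2]) <= 0 ||
          co$grate[1] - 0.99 * abs(co$grate[2]) <= 0)
        stop("gamma confounder parameters not positive after truncation")
      tb <- pmin(pmax(b, -0.99), 0.99)
      specs$W6 <- list(type = "gamma", shape = co$gshape[1] + co$gshape[2] * tb,
                       rate = co$grate[1] + co$grate[2] * tb)
    }
    W <- sample_gaussian_copula(specs, co$copula, n)
    cbind(data.frame(B = b), W)
  })
}

exposure_eta <- function(config) {
  inflate_positivity(config$coeff$eta, config$positivity_level)
}

# ---- calibration -------------------------------------------------------------

#' Calibrate the scenario's intercepts on dedicated large samples
#'
#' Fixes (i) the exposure intercept so the marginal prevalence hits
#' `target_prev` at the scenario's positivity level and (ii) the missingness
#' intercepts so each indicator hits its target marginal rate, using fresh
#' calibration samples of `n_cal` rows seeded from the master seed.  The
#' intercepts are frozen in the returned config and reused for all replicates.
#'
#' @param config a [scenario_config()].
#' @return the config with its `calibration` slot filled.
#' @export
calibrate_scenario <- function(config) {
  seed_e <- derive_seed(config$master_seed, 0L, "calibrate-exposure")
  cal <- sample_confounders(config, config$n_cal, seed_e)
  eta <- exposure_eta(config)
  X <- exposure_design(cal, config$dgp_id)
  lp <- drop(X[, names(eta), drop = FALSE] %*% eta)
  eta0 <- calibrate_intercept(config$target_prev, lp)

  # complete calibration data (exposure + outcome) for the missingness models
  seed_m <- derive_seed(config$master_seed, 0L, "calibrate-missingness")
  set.seed(seed_m)
  cal$A <- rbinom(nrow(cal), 1, plogis(eta0 + lp))
  Xy <- outcome_design(cal, config$dgp_id)
  ups <- config$coeff$upsilon
  cal$Y <- rnorm(nrow(cal), config$coeff$upsilon0 +
                   drop(Xy[, names(ups), drop = FALSE] %*% ups), 1)
  spec <- build_mdag(config$mdag, config$dgp_id, config$coeff$miss)
  mi <- calibrate_mdag_intercepts(cal, spec)

  config$calibration <- list(eta0 = eta0, miss_intercepts = mi,
                             positivity_level = config$positivity_level)
  config
}

#' Generate one complete (pre-missingness) dataset
#'
#' Draws the auxiliary B, the confounders (through the Gaussian copula), the
#' exposure from the level-inflated interaction model with its calibrated
#' intercept, and the continuous outcome `Y ~ Normal(outcome linear predictor,
#' 1)`.  The true propensity specification is attached as attribute
#' `"propensity"`.
#'
#' @param config a [scenario_config()]; calibrated automatically if needed.
#' @param rep_index replicate index (>= 1) driving the seed stream.
#' @return data.frame with columns B, W1..W5 (W6 for DGP 5), A, Y.
#' @export
generate_complete_data <- function(config, rep_index = 1L) {
  if (is.null(config$calibration)) config <- calibrate_scenario(config)
  seed <- derive_seed(config$master_seed, rep_index, "complete")
  dat <- sample_confounders(config, config$n, seed)
  eta <- exposure_eta(config)
  eta0 <- config$calibration$eta0
  X <- exposure_design(dat, config$dgp_id)
  lp <- eta0 + drop(X[, names(eta), drop = FALSE] %*% eta)
  dat$A <- rbinom(config$n, 1, plogis(lp))
  ups <- config$coeff$upsilon
  Xy <- outcome_design(dat, config$dgp_id)
  dat$Y <- rnorm(config$n, config$coeff$upsilon0 +
                   drop(Xy[, names(ups), drop = FALSE] %*% ups), 1)
  attr(dat, "propensity") <- list(eta0 = eta0, eta = eta, dgp_id = config$dgp_id)
  attr(dat, "dgp_id") <- config$dgp_id
  dat
}

#' Proportion of records with a near-positivity violation
#'
#' Re-estimates the true-form logistic exposure model on the data, computes
#' fitted propensity scores, and returns the proportion of records with
#' `min(p, 1-p) < cutoff`.  Falls back to the generating coefficients with a
#' warning if the refit fails to converge.
#'
#' @param data complete dataset from [generate_complete_data()].
#' @param config the scenario config it was generated under.
#' @param cutoff violation threshold (0.002).
#' @return proportion in `[0, 1]`.
#' @export
quantify_positivity <- function(data, config, cutoff = 0.002) {
  X <- exposure_design(data, config$dgp_id)
  fit <- suppressWarnings(glm.fit(cbind(`(Intercept)` = 1, X), data$A,
                                  family = binomial()))
  if (!fit$converged || anyNA(fit$coefficients)) {
    warning("propensity refit did not converge; using generating coefficients")
    pr <- attr(data, "propensity")
    p <- plogis(pr$eta0 + drop(X[, names(pr$eta), drop = FALSE] %*% pr$eta))
  } else {
    p <- fit$fitted.values
  }
  mean(pmin(p, 1 - p) < cutoff)
}
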