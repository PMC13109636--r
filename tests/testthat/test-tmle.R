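test_that("outcome scaling round-trips and preserves a linear ATE", {
  s <- scale_outcome(c(2, 4, 6))
  expect_equal(s$y01, c(0, 0.5, 1))
  expect_equal(s$y01 * diff(s$bounds) + s$bounds[1], c(2, 4, 6))
  expect_error(scale_outcome(rep(3, 5)), "constant")
  # a difference of means scales back exactly
  y <- rnorm(100); a <- rep(0:1, 50)
  s2 <- scale_outcome(y)
  dm01 <- mean(s2$y01[a == 1]) - mean(s2$y01[a == 0])
  expect_equal(dm01 * diff(s2$bounds), mean(y[a == 1]) - mean(y[a == 0]))
})

test_that("propensity truncation and clever covariates follow the formulas", {
  expect_equal(truncate_ps(c(0.005, 0.5, 0.999)), c(0.01, 0.5, 0.99))
  h <- clever_covariates(c(1, 0), c(0.25, 0.25))
  expect_equal(h$H1, c(4, 0))
  expect_equal(h$H0, c(0, 4 / 3))
  expect_equal(h$H_at_A, c(4, -4 / 3))
  set.seed(3)
  A <- rbinom(500, 1, 0.4); g <- truncate_ps(runif(500))
  hh <- clever_covariates(A, g)
  expect_equal(mean(hh$H1 * g), mean(A)) # inverse-weight identity
})

test_that("fluctuation solves the score equations (vs a Newton oracle)", {
  # hand-set toy: 6 records
  Q1 <- c(0.3, 0.4, 0.5, 0.6, 0.2, 0.7)
  Q0 <- c(0.2, 0.3, 0.6, 0.5, 0.4, 0.3)
  A <- c(1, 0, 1, 0, 1, 0)
  g <- c(0.3, 0.5, 0.7, 0.4, 0.2, 0.6)
  y01 <- c(0.9, 0.1, 0.4, 0.8, 0.3, 0.5)
  fl <- fluctuate(Q0, Q1, y01, A, g)
  H1 <- A / g; H0 <- (1 - A) / (1 - g)
  off <- qlogis(ifelse(A == 1, Q1, Q0))
  score <- function(e) {
    p <- plogis(off + e[1] * H1 + e[2] * H0)
    c(sum(H1 * (y01 - p)), sum(H0 * (y01 - p)))
  }
  e <- c(0, 0) # independent 2-D Newton solve of the same equations
  for (i in 1:50) {
    p <- plogis(off + e[1] * H1 + e[2] * H0)
    wt <- p * (1 - p)
    J <- -rbind(c(sum(H1^2 * wt), sum(H1 * H0 * wt)),
                c(sum(H1 * H0 * wt), sum(H0^2 * wt)))
    e <- e - solve(J, score(e))
  }
  expect_equal(fl$eps, e, tolerance = 1e-6)
  expect_lt(max(abs(score(fl$eps))) / 6, 1e-6)
  # targeting property on the updated predictions
  QsA <- ifelse(A == 1, fl$Qstar1, fl$Qstar0)
  expect_lt(abs(mean(H1 * (y01 - QsA))), 1e-6)
  expect_lt(abs(mean(H0 * (y01 - QsA))), 1e-6)
  # if the initial fit is already perfect, epsilon is zero
  fl0 <- fluctuate(Q0, Q1, ifelse(A == 1, Q1, Q0), A, g)
  expect_equal(fl0$eps, c(0, 0), tolerance = 1e-7)
})

test_that("TMLE matches the difference in means under randomization", {
  d <- toy_trial(4000, ate = 0.5, seed = 10)
  fit <- tmle_ate(d, sl_spec(c("glm", "glm_int", "mean"), folds = 5, seed = 11))
  dm <- mean(d$Y[d$A == 1]) - mean(d$Y[d$A == 0])
  expect_equal(fit$ate, dm, tolerance = 0.05)
  expect_true(fit$ci[1] <= fit$ate && fit$ate <= fit$ci[2])
  expect_gt(fit$se, 0)
  expect_error(tmle_ate(transform(d, A = 0)), "arm")
})

test_that("targeting drives the EIC score below 1e-6", {
  cfg <- cached_scenario(1, 1, "A", n = 2000)
  dat <- generate_complete_data(cfg, 5)
  sls <- sl_spec(c("glm", "glm_int", "mean"), folds = 10, seed = 12)
  W <- dat[, c("W1", "W2", "W3", "W4", "W5")]
  sc <- scale_outcome(dat$Y)
  fQ <- fit_super_learner(cbind(A = dat$A, W), sc$y01, sls)
  Q1 <- pmin(pmax(fQ$predict(cbind(A = 1, W)), 1e-6), 1 - 1e-6)
  Q0 <- pmin(pmax(fQ$predict(cbind(A = 0, W)), 1e-6), 1 - 1e-6)
  fg <- fit_super_learner(W, dat$A, sls, family = "binomial")
  g <- truncate_ps(fg$predict(W))
  fl <- fluctuate(Q0, Q1, sc$y01, dat$A, g)
  QsA <- ifelse(dat$A == 1, fl$Qstar1, fl$Qstar0)
  expect_lt(abs(mean((dat$A / g) * (sc$y01 - QsA))), 1e-6)
  expect_lt(abs(mean(((1 - dat$A) / (1 - g)) * (sc$y01 - QsA))), 1e-6)
  # the influence curve is centered after targeting
  psi <- mean(fl$Qstar1 - fl$Qstar0)
  ic <- (fl$H1 - fl$H0) * (sc$y01 - QsA) + fl$Qstar1 - fl$Qstar0 - psi
  expect_lt(abs(mean(ic)), 1e-6)
})

test_that("extended TMLE reduces to plain TMLE without outcome missingness", {
  d <- toy_trial(1500, seed = 13)
  d$M_Y <- 0L
  sls <- sl_spec(c("glm", "mean"), folds = 5, seed = 14)
  f1 <- tmle_ext(d, sls)
  f2 <- tmle_ate(d[, setdiff(names(d), "M_Y")], sls)
  expect_equal(f1$ate, f2$ate, tolerance = 1e-10)
  expect_equal(f1$se, f2$se, tolerance = 1e-10)
})

test_that("extended TMLE is consistent under MCAR outcome missingness", {
  set.seed(15)
  reps <- 60
  est <- numeric(reps)
  sls <- fast_sl()
  for (r in 1:reps) {
    d <- toy_trial(1200, ate = 0.5, seed = 1500 + r)
    d$M_Y <- rbinom(nrow(d), 1, 0.2)
    d$Y[d$M_Y == 1] <- NA
    est[r] <- tmle_ext(d, sls)$ate
  }
  expect_lt(abs(mean(est) - 0.5), 3 * sd(est) / sqrt(reps))
  # inverse-probability weights average to ~1 (identity check on one draw)
  d <- toy_trial(20000, seed = 16)
  d$M_Y <- rbinom(nrow(d), 1, 0.25)
  r1 <- 0.75
  expect_equal(mean((d$M_Y == 0) / r1), 1, tolerance = 0.02)
})

test_that("dataset strategies keep the right records", {
  cfg <- cached_scenario(1, 1, "B", n = 4000)
  obsd <- generate_observed_data(cfg, 1)
  ind <- obsd[, grep("^M_", names(obsd))]

  cc <- prepare_cc(obsd)
  expect_equal(nrow(cc), sum(rowSums(ind) == 0))
  expect_false(anyNA(cc))
  expect_equal(nrow(cc) / nrow(obsd), 0.5, tolerance = 0.1)

  ext <- prepare_ext(obsd)
  expect_equal(nrow(ext), sum(obsd$M_A == 0 & obsd$M_W2 == 0 &
                                obsd$M_W3 == 0 & obsd$M_W4 == 0))
  expect_true("M_Y" %in% names(ext))
  expect_gte(nrow(ext), nrow(cc))
  expect_true(anyNA(ext$Y)) # outcomes stay, masked

  mc <- prepare_ext_mcmi(obsd)
  expect_equal(nrow(mc), sum(obsd$M_A == 0))
  expect_false(anyNA(mc[, c("W2", "W3", "W4")])) # filled
  expect_true(all(c("M_W2", "M_W3", "M_W4", "M_Y") %in% names(mc)))
  # filled cells equal the indicator counts among retained rows
  expect_equal(sum(mc$M_W2 + mc$M_W3 + mc$M_W4),
               sum(ind[obsd$M_A == 0, c("M_W2", "M_W3", "M_W4")]))
  # complete input passes through with all-zero indicators
  comp <- generate_complete_data(cfg, 2)
  spec <- build_mdag("B", 1)
  ic <- setNames(rep(-30, 5), names(spec$nodes))
  o2 <- apply_missingness(comp, spec, seed = 1, intercepts = ic)
  expect_equal(prepare_ext_mcmi(o2)[, names(comp)], comp, ignore_attr = TRUE)
})

test_that("TMLE is doubly robust when one nuisance model is wrong", {
  # outcome model trimmed to two-way interactions so the interaction GLM is
  # the exact outcome form
  co <- default_coefficients(1)
  co$upsilon[grep(":.*:", names(co$upsilon))] <- 0
  reps <- 80
  estQ <- estG <- numeric(reps)
  cfg <- cached_scenario(1, 1, "A", n = 2000, master_seed = 606, coeff = co)
  slQ <- sl_spec("glm_int", seed = 20) # true-form outcome model
  slM <- sl_spec("mean", seed = 21)
  for (r in 1:reps) {
    dat <- generate_complete_data(cfg, r)
    W <- dat[, c("W1", "W2", "W3", "W4", "W5")]
    sc <- scale_outcome(dat$Y)
    n <- nrow(dat)
    # route 1: good Q (true form), useless g (constant prevalence)
    fQ <- fit_super_learner(cbind(A = dat$A, W), sc$y01, slQ)
    Q1 <- pmin(pmax(fQ$predict(cbind(A = 1, W)), 1e-6), 1 - 1e-6)
    Q0 <- pmin(pmax(fQ$predict(cbind(A = 0, W)), 1e-6), 1 - 1e-6)
    flQ <- fluctuate(Q0, Q1, sc$y01, dat$A, rep(0.15, n))
    estQ[r] <- mean(flQ$Qstar1 - flQ$Qstar0) * diff(sc$bounds)
    # route 2: useless Q (mean learner), good g (true form incl. B)
    fQm <- fit_super_learner(cbind(A = dat$A, W), sc$y01, slM)
    Qm <- pmin(pmax(fQm$predict(cbind(A = 1, W)), 1e-6), 1 - 1e-6)
    Xg <- exposure_design(dat, 1)
    eta_l <- inflate_positivity(cfg$coeff$eta, cfg$positivity_level)
    gtrue <- plogis(cbind(1, Xg) %*%
                      c(cfg$calibration$eta0, eta_l[colnames(Xg)]))
    flG <- fluctuate(Qm, Qm, sc$y01, dat$A, truncate_ps(as.numeric(gtrue)))
    estG[r] <- mean(flG$Qstar1 - flG$Qstar0) * diff(sc$bounds)
  }
  expect_lt(abs(mean(estQ) - cfg$true_ate), 3 * sd(estQ) / sqrt(reps))
  expect_lt(abs(mean(estG) - cfg$true_ate), 3 * sd(estG) / sqrt(reps))
})

test_that("confidence intervals shrink at the root-n rate", {
  widths <- vapply(c(500, 2000, 8000), function(n) {
    cfg <- cached_scenario(1, 1, "A", n = n, master_seed = 77)
    w <- vapply(1:4, function(r) {
      f <- tmle_ate(generate_complete_data(cfg, r), fast_sl())
      f$ci[2] - f$ci[1]
    }, numeric(1))
    mean(w)
  }, numeric(1))
  expect_equal(widths[1] / widths[2], 2, tolerance = 0.15)
  expect_equal(widths[2] / widths[3], 2, tolerance = 0.15)
})
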