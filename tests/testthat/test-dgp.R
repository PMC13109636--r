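test_that("Gaussian copula reproduces its marginals and dependence", {
  n <- 100000
  corr <- matrix(c(1, 0.6, 0.6, 1), 2)
  # normal margins: the latent correlation carries through exactly
  tab <- sample_gaussian_copula(
    list(x = list(type = "normal", mean = 0, sd = 1),
         y = list(type = "normal", mean = 0, sd = 1)), corr, n, seed = 1)
  expect_equal(cor(tab$x, tab$y), 0.6, tolerance = 0.02)
  expect_lt(ks.test(tab$x, pnorm)$statistic, 0.01)

  # identity correlation: independence; Bernoulli margin preserved under corr
  specs <- list(b = list(type = "bernoulli", p = 0.3),
                g = list(type = "gamma", shape = 2, rate = 1),
                z = list(type = "normal", mean = 1, sd = 2))
  tab2 <- sample_gaussian_copula(specs, diag(3), n, seed = 2)
  expect_lt(abs(mean(tab2$b) - 0.3), 0.01)
  expect_lt(abs(cor(tab2$g, tab2$z, method = "spearman")), 0.01)
  expect_lt(ks.test(tab2$g, pgamma, shape = 2, rate = 1)$statistic, 0.01)

  corr3 <- matrix(c(1, 0.5, 0.5, 1), 2)
  tab3 <- sample_gaussian_copula(
    list(b = list(type = "bernoulli", p = 0.3),
         z = list(type = "normal", mean = 0, sd = 1)), corr3, n, seed = 3)
  expect_lt(abs(mean(tab3$b) - 0.3), 0.01)
  expect_gt(cor(tab3$b, tab3$z), 0.2) # dependence induced

  bad <- matrix(c(1, 2, 2, 1), 2)
  expect_error(sample_gaussian_copula(
    list(x = list(type = "normal", mean = 0, sd = 1),
         y = list(type = "normal", mean = 0, sd = 1)), bad, 10),
    "positive definite")
})

test_that("softmax categories follow the stated probabilities", {
  b <- rnorm(5)
  pr <- softmax_probs(b, c(0, 0, 0, 0), c(0, 0, 0, 0))
  expect_equal(unname(pr), matrix(0.25, 5, 4))
  pr2 <- softmax_probs(b, c(1, 0, 0, 0), c(0, 0, 0, 0))
  expect_equal(pr2[, 1], rep(exp(1) / (exp(1) + 3), 5))
  pr3 <- softmax_probs(b, c(0.5, -0.2, 0.1, 0), c(0.4, -0.3, 0.2, 0))
  expect_equal(rowSums(pr3), rep(1, 5))
  draws <- sample_categorical_softmax(rep(0, 200000), c(1, 0, 0, 0),
                                      c(0, 0, 0, 0), seed = 4)
  expect_equal(mean(draws == 1), exp(1) / (exp(1) + 3), tolerance = 0.01)
})

test_that("gamma confounder uses truncated B in shape and rate", {
  # b beyond the truncation range is clamped to +/- 0.99
  x <- sample_gamma_confounder(rep(2, 100000), 2, 1, 2, 0, seed = 5)
  y <- sample_gamma_confounder(rep(0.99, 100000), 2, 1, 2, 0, seed = 5)
  expect_identical(x, y)
  expect_equal(mean(x), 2.99 / 2, tolerance = 0.02)
  # xi1 = tau1 = 0: plain gamma with mean xi0/tau0
  z <- sample_gamma_confounder(rnorm(100000), 3, 0, 1.5, 0, seed = 6)
  expect_equal(mean(z), 2, tolerance = 0.03)
  expect_true(all(z > 0))
  expect_error(sample_gamma_confounder(0, 0.5, 1, 2, 0), "positive")
})

test_that("positivity inflation doubles interaction coefficients per level", {
  eta <- c(W1 = 0.5, "W1:W3" = 0.5, "W3:W4" = -0.8)
  expect_identical(inflate_positivity(eta, 1), eta)
  l2 <- inflate_positivity(eta, 2)
  expect_equal(unname(l2["W1:W3"]), 1.0)
  expect_equal(unname(l2["W1"]), 0.5) # main effects untouched
  l3 <- inflate_positivity(eta, 3)
  expect_equal(unname(l3["W1:W3"]), 2.0)
  expect_equal(unname(l3["W3:W4"]), -3.2)
  expect_error(inflate_positivity(eta, 4), "level")
})

test_that("intercept calibration solves the marginal to 1e-6", {
  expect_equal(calibrate_intercept(0.5, rep(0, 10)), 0, tolerance = 1e-8)
  expect_equal(calibrate_intercept(0.15, rep(0, 10)), qlogis(0.15),
               tolerance = 1e-8)
  set.seed(7)
  lp <- rnorm(5000)
  c1 <- calibrate_intercept(0.15, lp)
  expect_lt(abs(mean(plogis(c1 + lp)) - 0.15), 1e-6)
  # independent bisection oracle on the same sample
  lo <- -20; hi <- 20
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (mean(plogis(mid + lp)) < 0.15) lo <- mid else hi <- mid
  }
  expect_equal(c1, (lo + hi) / 2, tolerance = 1e-6)
  # monotone in the target
  expect_lt(c1, calibrate_intercept(0.3, lp))
  expect_error(calibrate_intercept(1.2, lp), "target")
})

test_that("complete-data generator is calibrated and reproducible", {
  cfg <- cached_scenario(1, 1, "A", n = 50000)
  dat <- generate_complete_data(cfg, 1)
  expect_equal(mean(dat$A), 0.15, tolerance = 0.012)
  expect_true(all(dat$W1 %in% 0:1) && all(dat$W5 %in% 0:1))
  expect_false(anyNA(dat))
  # bit-identical regeneration for the same config and replicate
  expect_identical(dat, generate_complete_data(cfg, 1))
  expect_false(identical(dat$B, generate_complete_data(cfg, 2)$B))
})

test_that("column types follow the DGP id", {
  for (d in c(1, 2, 4, 5)) {
    cfg <- cached_scenario(d, 1, "A", n = 3000, n_cal = 10000)
    dat <- generate_complete_data(cfg, 1)
    if (d == 1) expect_true(all(dat$W4 %in% 0:1))
    if (d >= 2) expect_gt(length(unique(dat$W4)), 10)
    if (d >= 4) expect_true(all(dat$W3 %in% 1:4) && length(unique(dat$W3)) == 4)
    if (d == 5) expect_true(all(dat$W6 > 0))
    if (d < 5) expect_null(dat$W6)
  }
})

test_that("regressing Y on the true design recovers the true ATE", {
  cfg <- cached_scenario(1, 1, "A", n = 50000)
  dat <- generate_complete_data(cfg, 1)
  X <- outcome_design(dat, 1)
  fit <- lm.fit(cbind(1, X), dat$Y)
  se_approx <- 1 / sqrt(nrow(dat) * mean(dat$A) * (1 - mean(dat$A)))
  expect_lt(abs(fit$coefficients[2] - cfg$true_ate), 3 * se_approx)
})

test_that("positivity violations are rare at level 1 and grow with level", {
  n <- 50000
  viol <- vapply(1:3, function(l) {
    cfg <- cached_scenario(1, l, "A", n = n)
    quantify_positivity(generate_complete_data(cfg, 3), cfg)
  }, numeric(1))
  expect_lt(viol[1], 0.01)
  expect_true(all(diff(viol) > 0)) # nondecreasing gradient
  expect_gt(viol[3], 0.15)
})
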