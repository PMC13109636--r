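test_that("predictive mean matching draws from the donors' support", {
  set.seed(1)
  X_obs <- data.frame(x = rnorm(50))
  X_mis <- data.frame(x = rnorm(10))
  expect_equal(impute_pmm(rep(7, 50), X_obs, X_mis, seed = 2), rep(7, 10))
  y <- 2 * X_obs$x + rnorm(50, 0, 0.1)
  imp <- impute_pmm(y, X_obs, X_mis, seed = 3)
  expect_true(all(imp %in% y))
  # well-separated clusters: targets match donors from their own cluster
  xo <- c(rnorm(40, -6, 0.3), rnorm(40, 6, 0.3))
  yo <- c(rnorm(40, -10, 0.2), rnorm(40, 10, 0.2))
  xm <- c(rnorm(20, -6, 0.3), rnorm(20, 6, 0.3))
  im <- impute_pmm(yo, data.frame(x = xo), data.frame(x = xm), seed = 4)
  expect_true(all(im[1:20] < 0) && all(im[21:40] > 0))
})

test_that("binary and polytomous imputation respect the category sets", {
  set.seed(5)
  Xo <- data.frame(x = rnorm(80)); Xm <- data.frame(x = rnorm(30))
  expect_equal(impute_binary(rep(0, 80), Xo, Xm, seed = 6), rep(0, 30))
  y <- rbinom(80, 1, plogis(3 * Xo$x))
  imp <- impute_binary(y, Xo, Xm, seed = 7)
  expect_true(all(imp %in% 0:1))
  expect_gt(mean(imp[Xm$x > 1]), mean(imp[Xm$x < -1])) # pattern recovered
  yc <- sample(1:4, 120, replace = TRUE)
  impc <- impute_polytomous(yc, data.frame(x = rnorm(120)), Xm, seed = 8)
  expect_true(all(impc %in% 1:4))
})

test_that("tree-based imputation samples donors from terminal nodes", {
  set.seed(9)
  Xo <- data.frame(x = runif(400, -1, 1))
  Xm <- data.frame(x = runif(100, -1, 1))
  y <- as.numeric(Xo$x > 0)
  imp <- impute_cart(y, Xo, Xm, seed = 10)
  expect_true(all(imp %in% y))
  expect_gt(mean(imp == (Xm$x > 0)), 0.95) # step function recovered
  impf <- impute_rf(y, Xo, Xm, ntrees = 10, seed = 11)
  expect_true(all(impf %in% y))
  expect_gt(mean(impf == (Xm$x > 0)), 0.9)
  # rf imputation beats marginal draws on a smooth signal
  ys <- sin(3 * Xo$x) + rnorm(400, 0, 0.1)
  truth <- sin(3 * Xm$x)
  imps <- impute_rf(ys, Xo, Xm, ntrees = 10, seed = 12)
  marg <- sample(ys, 100, replace = TRUE)
  expect_lt(mean((imps - truth)^2), mean((marg - truth)^2))
})

test_that("interaction expansion drops collinear products", {
  tab <- data.frame(a = c(0, 1, 0, 1), b = c(0, 0, 1, 1), c = c(1, 1, 0, 0))
  out <- build_interactions(tab, orders = 2)
  expect_equal(ncol(out), 3 + 2) # b*c duplicates nothing but a*? checked below
  # b and c are complementary: b*c is constant zero and dropped
  expect_false("b.x.c" %in% names(out))
  expect_true(all(c("a.x.b", "a.x.c") %in% names(out)))
  out3 <- build_interactions(data.frame(x = rnorm(10), y = rnorm(10),
                                        z = rnorm(10)), orders = 2:3)
  expect_equal(ncol(out3), 3 + 3 + 1)
})

test_that("chained-equation imputation preserves observed cells", {
  cfg <- cached_scenario(1, 1, "B", n = 600)
  obsd <- generate_observed_data(cfg, 1)
  spec <- imputation_spec("cart", m = 3, iterations = 2, seed = 20)
  st <- fcs_impute(obsd, spec)
  expect_length(st$datasets, 3)
  vals <- obsd[, setdiff(names(obsd), grep("^M_", names(obsd), value = TRUE))]
  for (d in st$datasets) {
    expect_false(anyNA(d))
    for (cl in names(vals)) {
      o <- !is.na(vals[[cl]])
      expect_identical(d[[cl]][o], as.numeric(vals[[cl]][o])) # observed cells immutable
      if (all(vals[[cl]][o] %in% 0:1)) expect_true(all(d[[cl]] %in% 0:1))
    }
  }
  # no missing cells: the stack is m identical copies of the input
  comp <- generate_complete_data(cfg, 2)
  st2 <- fcs_impute(comp, imputation_spec("pmm", m = 2, iterations = 2, seed = 3))
  ref <- comp[, names(st2$datasets[[1]])]
  ref[] <- lapply(ref, as.numeric)
  expect_identical(st2$datasets[[1]], ref)
  expect_identical(st2$datasets[[1]], st2$datasets[[2]])
})

test_that("FCS recovers the mean of an MCAR outcome (linear-Gaussian toy)", {
  set.seed(21)
  n <- 2000
  d <- data.frame(x = rnorm(n))
  d$Y <- 1 + 2 * d$x + rnorm(n)
  full_mean <- mean(d$Y)
  d$Y[rbinom(n, 1, 0.3) == 1] <- NA
  st <- fcs_impute(d, imputation_spec("pmm", m = 10, iterations = 3, seed = 22))
  pooled <- mean(vapply(st$datasets, function(z) mean(z$Y), numeric(1)))
  expect_lt(abs(pooled - full_mean), 3 * sqrt(1 + 4) / sqrt(n))
})

test_that("EM on bootstrap samples recovers a bivariate normal", {
  set.seed(23)
  n <- 5000
  S <- matrix(c(1, 0.6, 0.6, 2), 2)
  X <- MASS::mvrnorm(n, c(1, -1), S)
  d <- data.frame(u = X[, 1], v = X[, 2])
  d$v[rbinom(n, 1, 0.3) == 1] <- NA
  st <- jm_norm_impute(d, imputation_spec("jm_norm", m = 5, seed = 24))
  expect_length(st$datasets, 5)
  for (z in st$datasets) {
    o <- !is.na(d$v)
    expect_identical(z$v[o], d$v[o])
    ev <- eigen(cov(as.matrix(z)), only.values = TRUE)$values
    expect_true(all(ev > 0)) # completed covariance stays PD
  }
  vbar <- mean(vapply(st$datasets, function(z) mean(z$v), numeric(1)))
  expect_lt(abs(vbar - (-1)), 3 * sqrt(2 / n) + 0.05)
  # no missing cells: identical copies
  d2 <- data.frame(u = rnorm(50), v = rnorm(50))
  st2 <- jm_norm_impute(d2, imputation_spec("jm_norm", m = 2, seed = 25))
  expect_identical(st2$datasets[[1]], st2$datasets[[2]])
})

test_that("Rubin's rules match the hand-computed worked example", {
  p <- rubin_pool(c(1, 3), c(1, 1), n_used = 100)
  expect_equal(p$qbar, 2)
  expect_equal(p$within, 1)
  expect_equal(p$between, 2)
  expect_equal(p$total_var, 1 + 1.5 * 2) # within + (1 + 1/m) * between
  expect_true(p$ci[1] <= p$qbar && p$qbar <= p$ci[2])
  # identical estimates: no between-imputation variance
  p0 <- rubin_pool(c(2, 2, 2), c(0.5, 0.5, 0.5), n_used = 50)
  expect_equal(p0$between, 0)
  expect_equal(p0$total_var, p0$within)
  expect_gte(p$total_var, p$within)
  expect_error(rubin_pool(1, 1), "at least 2")
})

test_that("MI analysis pools per-imputation TMLE fits", {
  cfg <- cached_scenario(1, 1, "A", n = 700)
  obsd <- generate_observed_data(cfg, 3)
  res <- mi_analyze(obsd, imputation_spec("cart", m = 3, iterations = 2,
                                          seed = 26), fast_sl())
  expect_s3_class(res$pooled, "pooled_estimate")
  expect_equal(res$ate, res$pooled$qbar)
  expect_gte(res$pooled$total_var, res$pooled$within)
  expect_true(res$ci[1] <= res$ate && res$ate <= res$ci[2])
})
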