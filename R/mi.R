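#' Multiple-imputation specification
#'
#' @param method one of `"pmm"` (parametric chained equations with predictive
#'   mean matching for the outcome), `"pmm_int"` (same with confounder
#'   interactions in the imputation models), `"cart"`, `"rf"`, `"jm_norm"`
#'   (joint multivariate normal via the EMB algorithm).
#' @param m number of imputations (study default 100).
#' @param iterations chained-equation sweeps (study default 10).
#' @param pmm_donors donor-pool size for predictive mean matching.
#' @param rf_trees trees per random-forest imputation model.
#' @param interaction_orders interaction orders added by `"pmm_int"`.
#' @param seed optional integer seed.
#' @return object of class `imputation_spec`.
#' @export
imputation_spec <- function(method = c("pmm", "pmm_int", "cart", "rf", "jm_norm"),
                            m = 100, iterations = 10, pmm_donors = 5,
                            rf_trees = 10, interaction_orders = 2:4,
                            seed = NULL) {
  method <- match.arg(method)
  stopifnot(m >= 2, iterations >= 1)
  structure(list(method = method, m = as.integer(m),
                 iterations = as.integer(iterations),
                 pmm_donors = as.integer(pmm_donors),
                 rf_trees = as.integer(rf_trees),
                 interaction_orders = interaction_orders, seed = seed),
            class = "imputation_spec")
}

imp_col_types <- function(vals) {
  vapply(names(vals), function(nm) {
    v <- na.omit(vals[[nm]])
    if (all(v %in% 0:1)) "binary"
    else if (all(v %in% 1:4) && length(unique(v)) > 2 &&
             all(v == round(v))) "categorical"
    else "continuous"
  }, character(1))
}

# Bayesian linear regression draw under a flat prior
blr_draw <- function(y, X) {
  qx <- qr(X)
  piv <- qx$pivot[seq_len(qx$rank)]
  Xr <- X[, piv, drop = FALSE]
  XtX <- crossprod(Xr)
  V <- solve(XtX + diag(1e-8 * max(1, max(diag(XtX))), ncol(Xr)))
  bh <- drop(V %*% crossprod(Xr, y))
  res <- y - drop(Xr %*% bh)
  df <- max(length(y) - length(piv), 1)
  sigma2 <- sum(res^2) / rchisq(1, df)
  bs <- bh + drop(t(chol((V + t(V)) / 2)) %*% rnorm(length(bh))) * sqrt(sigma2)
  list(cols = piv, beta_hat = bh, beta_star = bs, sigma = sqrt(sigma2))
}

#' Predictive mean matching imputation
#'
#' Draws regression parameters from their normal-inverse-gamma posterior;
#' donor predicted means use the posterior mode, target predicted means the
#' posterior draw (type-1 matching); each target receives the observed value
#' of one of its `k` nearest-predicted-mean donors, chosen uniformly.
#'
#' @param y_obs observed values of the variable under imputation.
#' @param X_obs,X_mis numeric predictor matrices for donors and targets.
#' @param k donor-pool size.
#' @param seed optional integer seed.
#' @return imputed values, a subset of `y_obs`.
#' @export
impute_pmm <- function(y_obs, X_obs, X_mis, k = 5, seed = NULL) {
  with_seed(seed, {
    if (var(y_obs) < 1e-12) return(rep(y_obs[1], nrow(X_mis)))
    Xo <- cbind(1, as.matrix(X_obs))
    Xm <- cbind(1, as.matrix(X_mis))
    d <- blr_draw(y_obs, Xo)
    yh_obs <- drop(Xo[, d$cols, drop = FALSE] %*% d$beta_hat)
    yh_mis <- drop(Xm[, d$cols, drop = FALSE] %*% d$beta_star)
    k <- min(k, length(y_obs))
    vapply(yh_mis, function(t) {
      dn <- abs(yh_obs - t)
      donors <- order(dn)[seq_len(k)]
      y_obs[donors[sample.int(k, 1)]]
    }, numeric(1))
  })
}

# Bayesian linear regression imputation (continuous confounders)
impute_norm <- function(y_obs, X_obs, X_mis, seed = NULL) {
  with_seed(seed, {
    Xo <- cbind(1, as.matrix(X_obs))
    Xm <- cbind(1, as.matrix(X_mis))
    d <- blr_draw(y_obs, Xo)
    drop(Xm[, d$cols, drop = FALSE] %*% d$beta_star) +
      rnorm(nrow(Xm), 0, d$sigma)
  })
}

#' Logistic-regression imputation with posterior coefficient draws
#'
#' @inheritParams impute_pmm
#' @return imputed 0/1 values.
#' @export
impute_binary <- function(y_obs, X_obs, X_mis, seed = NULL) {
  with_seed(seed, {
    if (length(unique(y_obs)) < 2) return(rep(y_obs[1], nrow(X_mis)))
    Xo <- cbind(1, as.matrix(X_obs))
    Xm <- cbind(1, as.matrix(X_mis))
    f <- suppressWarnings(glm.fit(Xo, y_obs, family = binomial()))
    piv <- f$qr$pivot[seq_len(f$rank)]
    R <- qr.R(f$qr)[seq_len(f$rank), seq_len(f$rank), drop = FALSE]
    V <- tryCatch(chol2inv(R), error = function(e) diag(1e-4, f$rank))
    bh <- f$coefficients[piv]
    bh[is.na(bh)] <- 0
    bs <- drop(MASS::mvrnorm(1, bh, (V + t(V)) / 2))
    p <- pmin(pmax(plogis(drop(Xm[, piv, drop = FALSE] %*% bs)), 1e-6), 1 - 1e-6)
    rbinom(nrow(Xm), 1, p)
  })
}

#' Polytomous-regression imputation with posterior coefficient draws
#'
#' @inheritParams impute_pmm
#' @return imputed categories from the observed category set.
#' @export
impute_polytomous <- function(y_obs, X_obs, X_mis, seed = NULL) {
  with_seed(seed, {
    lev <- sort(unique(y_obs))
    if (length(lev) < 2) return(rep(lev[1], nrow(X_mis)))
    d <- data.frame(.y = factor(y_obs, levels = lev), as.data.frame(X_obs))
    m <- nnet::multinom(.y ~ ., data = d, trace = FALSE, maxit = 200,
                        MaxNWts = 10000)
    cf <- coef(m)
    if (is.null(dim(cf))) cf <- matrix(cf, nrow = 1)
    theta <- as.vector(t(cf))
    V <- tryCatch(vcov(m), error = function(e) NULL)
    if (!is.null(V) && all(is.finite(V)))
      theta <- drop(MASS::mvrnorm(1, theta, (V + t(V)) / 2))
    cfs <- matrix(theta, nrow = nrow(cf), byrow = TRUE)
    Xm <- cbind(1, as.matrix(X_mis))
    lp <- cbind(0, Xm %*% t(cfs)) # baseline category first
    lp <- lp - apply(lp, 1, max)
    pr <- exp(lp) / rowSums(exp(lp))
    cp <- t(apply(pr, 1, cumsum))
    u <- runif(nrow(Xm))
    lev[1 + rowSums(u > cp[, -ncol(cp), drop = FALSE])]
  })
}

rpart_nodes <- function(fit, newdata) {
  nf <- fit
  nf$frame$yval <- as.numeric(row.names(fit$frame))
  as.integer(predict(nf, newdata = newdata, type = "vector"))
}

#' CART imputation: donor sampling within terminal nodes
#'
#' Fits a regression or classification tree (minimum leaf 5, complexity
#' 1e-4), drops each target down the tree, and samples uniformly one donor's
#' observed value from its terminal node.
#'
#' @inheritParams impute_pmm
#' @param categorical fit a classification tree on a factor response.
#' @return imputed values, a subset of `y_obs`.
#' @export
impute_cart <- function(y_obs, X_obs, X_mis, seed = NULL, categorical = FALSE) {
  with_seed(seed, {
    Xo <- as.data.frame(X_obs)
    Xm <- as.data.frame(X_mis)
    yy <- if (categorical) factor(y_obs) else y_obs
    d <- data.frame(.y = yy, Xo)
    fit <- rpart::rpart(.y ~ ., data = d,
                        method = if (categorical) "class" else "anova",
                        control = rpart::rpart.control(minbucket = 5,
                                                       cp = 1e-4, xval = 0))
    node_obs <- as.integer(row.names(fit$frame))[fit$where]
    node_mis <- rpart_nodes(fit, Xm)
    vapply(node_mis, function(nd) {
      donors <- which(node_obs == nd)
      if (!length(donors)) donors <- seq_along(y_obs)
      y_obs[donors[sample.int(length(donors), 1)]]
    }, numeric(1))
  })
}

#' Random-forest imputation: donor sampling across trees
#'
#' Fits `ntrees` bootstrap trees with random feature subsets; for each target
#' a tree is drawn at random and one donor value is sampled uniformly from
#' the target's terminal node in that tree.
#'
#' @inheritParams impute_cart
#' @param ntrees number of trees.
#' @return imputed values, a subset of `y_obs`.
#' @export
impute_rf <- function(y_obs, X_obs, X_mis, ntrees = 10, seed = NULL,
                      categorical = FALSE) {
  with_seed(seed, {
    Xo <- as.data.frame(X_obs)
    Xm <- as.data.frame(X_mis)
    yy <- if (categorical) factor(y_obs) else y_obs
    d <- data.frame(.y = yy, Xo)
    rf <- ranger::ranger(.y ~ ., data = d, num.trees = ntrees,
                         min.node.size = 5, num.threads = 1,
                         seed = sample.int(.Machine$integer.max, 1))
    no <- predict(rf, Xo, type = "terminalNodes", num.threads = 1)$predictions
    nm <- predict(rf, Xm, type = "terminalNodes", num.threads = 1)$predictions
    if (is.null(dim(nm))) nm <- matrix(nm, nrow = nrow(Xm))
    vapply(seq_len(nrow(Xm)), function(i) {
      tr <- sample.int(ntrees, 1)
      donors <- which(no[, tr] == nm[i, tr])
      if (!length(donors)) donors <- seq_along(y_obs)
      y_obs[donors[sample.int(length(donors), 1)]]
    }, numeric(1))
  })
}

#' Append interaction products of confounder columns
#'
#' Products of the supplied numeric columns up to the requested orders are
#' appended as predictors; exact-duplicate and zero-variance products are
#' dropped.
#'
#' @param tab numeric data.frame.
#' @param orders subset of `{2, 3, 4}`.
#' @param base names of the columns to interact (default: all).
#' @return expanded data.frame.
#' @export
build_interactions <- function(tab, orders = 2:4, base = names(tab)) {
  out <- tab
  n <- nrow(tab)
  # cheap two-projection fingerprint: exact duplicates always collide,
  # random collisions are numerically negligible
  w1 <- sin(seq_len(n) * 1.2345678)
  w2 <- cos(seq_len(n) * 2.3456789)
  keyf <- function(v) paste(signif(sum(v * w1), 10), signif(sum(v * w2), 10))
  keys <- vapply(tab, keyf, character(1))
  for (ord in sort(orders)) {
    for (cs in utils::combn(base, ord, simplify = FALSE)) {
      v <- Reduce(`*`, tab[cs])
      if (var(v) < 1e-12) next
      k <- keyf(v)
      if (k %in% keys) next
      nm <- paste(cs, collapse = ".x.")
      out[[nm]] <- v
      keys <- c(keys, k)
    }
  }
  out
}

# predictor frame for one target column: all other variables (incl. B and Y)
imp_predictors <- function(filled, target, types, method, orders = 2:4) {
  X <- filled[, setdiff(names(filled), target), drop = FALSE]
  tree <- method %in% c("cart", "rf")
  if ("W3" %in% names(X) && types[["W3"]] == "categorical") {
    if (tree) X$W3 <- factor(X$W3)
    else {
      X$W3_2 <- as.numeric(X$W3 == 2)
      X$W3_3 <- as.numeric(X$W3 == 3)
      X$W3_4 <- as.numeric(X$W3 == 4)
      X$W3 <- NULL
    }
  }
  if (method == "pmm_int") {
    conf <- grep("^W", names(X), value = TRUE)
    X <- build_interactions(X, orders, base = conf)
  }
  X
}

#' Chained-equation (FCS) multiple imputation
#'
#' Missing cells are first filled by random draws from each column's observed
#' values; incomplete columns are then visited in order of increasing
#' missingness, refitting the type-appropriate univariate model on the other
#' (currently completed) variables, including the auxiliary B and the
#' outcome, and redrawing imputations; the sweep is repeated
#' `spec$iterations` times and the whole chain `spec$m` times with
#' independent streams.
#'
#' @param obs ObservedData from [apply_missingness()] (indicator columns are
#'   ignored; missingness is read from the `NA` pattern).
#' @param spec an [imputation_spec()] with method `"pmm"`, `"pmm_int"`,
#'   `"cart"` or `"rf"`.
#' @return object of class `imputed_stack`: list with `datasets` (m completed
#'   data.frames) and `trace` (per chain/iteration/column mean and sd of the
#'   imputed values).
#' @export
fcs_impute <- function(obs, spec = imputation_spec("pmm")) {
  vals <- obs[, setdiff(names(obs), indicator_cols(obs)), drop = FALSE]
  vals[] <- lapply(vals, as.numeric) # uniform storage across imputations
  types <- imp_col_types(vals)
  miss_n <- colSums(is.na(vals))
  if (any(miss_n == nrow(vals))) stop("column fully missing")
  visit <- names(sort(miss_n[miss_n > 0]))
  base_seed <- if (is.null(spec$seed)) sample.int(1e6, 1) else spec$seed
  datasets <- vector("list", spec$m)
  trace <- list()
  for (ch in seq_len(spec$m)) {
    set.seed(derive_seed(base_seed, ch, paste0("fcs-", spec$method)))
    filled <- vals
    for (cl in visit) {
      mis <- is.na(vals[[cl]])
      filled[[cl]][mis] <- sample(vals[[cl]][!mis], sum(mis), replace = TRUE)
    }
    if (length(visit)) for (it in seq_len(spec$iterations)) {
      for (cl in visit) {
        mis <- is.na(vals[[cl]])
        X <- imp_predictors(filled, cl, types, spec$method,
                            spec$interaction_orders)
        yo <- filled[[cl]][!mis]
        Xo <- X[!mis, , drop = FALSE]
        Xm <- X[mis, , drop = FALSE]
        dr <- switch(spec$method,
          pmm = , pmm_int = {
            ty <- types[[cl]]
            if (cl == "Y") impute_pmm(yo, Xo, Xm, k = spec$pmm_donors)
            else if (ty == "binary") impute_binary(yo, Xo, Xm)
            else if (ty == "categorical") impute_polytomous(yo, Xo, Xm)
            else impute_norm(yo, Xo, Xm)
          },
          cart = impute_cart(yo, Xo, Xm,
                             categorical = types[[cl]] == "categorical"),
          rf = impute_rf(yo, Xo, Xm, ntrees = spec$rf_trees,
                         categorical = types[[cl]] == "categorical"))
        filled[[cl]][mis] <- as.numeric(dr)
        trace[[length(trace) + 1]] <- data.frame(
          chain = ch, iteration = it, column = cl,
          mean = mean(as.numeric(dr)), sd = sd(as.numeric(dr)))
      }
    }
    datasets[[ch]] <- filled
  }
  structure(list(datasets = datasets,
                 trace = if (length(trace)) do.call(rbind, trace) else NULL,
                 method = spec$method),
            class = "imputed_stack")
}

# ---- joint multivariate normal MI (EMB) -------------------------------------

em_mvnorm <- function(X, max_iter = 500, tol = 1e-6) {
  n <- nrow(X); p <- ncol(X)
  mu <- colMeans(X, na.rm = TRUE)
  S <- stats::cov(X, use = "pairwise.complete.obs")
  S[!is.finite(S)] <- 0
  S <- S + diag(1e-6 + 1e-3 * mean(diag(S)), p)
  pat <- apply(is.na(X), 1, function(r) paste(which(r), collapse = ","))
  groups <- split(seq_len(n), pat)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    sx <- numeric(p); sxx <- matrix(0, p, p); ll <- 0
    for (g in groups) {
      misv <- which(is.na(X[g[1], ]))
      obsv <- setdiff(seq_len(p), misv)
      Xg <- X[g, , drop = FALSE]
      if (!length(misv)) {
        sx <- sx + colSums(Xg)
        sxx <- sxx + crossprod(Xg)
        ct <- chol(S)
        dev <- sweep(Xg, 2, mu)
        z <- dev %*% chol2inv(ct) * dev
        ll <- ll - 0.5 * length(g) * (p * log(2 * pi) + 2 * sum(log(diag(ct)))) -
          0.5 * sum(z)
        next
      }
      Soo <- S[obsv, obsv, drop = FALSE]
      ct <- chol(Soo)
      Sooi <- chol2inv(ct)
      Bm <- S[misv, obsv, drop = FALSE] %*% Sooi
      dev <- sweep(Xg[, obsv, drop = FALSE], 2, mu[obsv])
      Em <- matrix(mu[misv], length(g), length(misv), byrow = TRUE) +
        dev %*% t(Bm)
      Cm <- S[misv, misv, drop = FALSE] -
        Bm %*% S[obsv, misv, drop = FALSE]
      Eg <- Xg
      Eg[, misv] <- Em
      sx <- sx + colSums(Eg)
      cp <- crossprod(Eg)
      cp[misv, misv] <- cp[misv, misv, drop = FALSE] + length(g) * Cm
      sxx <- sxx + cp
      z <- dev %*% Sooi * dev
      ll <- ll - 0.5 * length(g) * (length(obsv) * log(2 * pi) +
                                      2 * sum(log(diag(ct)))) - 0.5 * sum(z)
    }
    mu <- sx / n
    S <- sxx / n - tcrossprod(mu)
    S <- (S + t(S)) / 2 + diag(1e-10, p)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * abs(ll_old)) {
      return(list(mu = mu, sigma = S, loglik = ll, iterations = it,
                  converged = TRUE))
    }
    ll_old <- ll
  }
  list(mu = mu, sigma = S, loglik = ll_old, iterations = max_iter,
       converged = FALSE)
}

#' Joint multivariate normal multiple imputation (EMB algorithm)
#'
#' For each of `m` imputations: bootstrap the rows, run EM to convergence for
#' the joint-normal `(mu, Sigma)` on the bootstrap sample, then impute the
#' original data's missing cells by a single draw from the conditional normal
#' given each row's observed cells under the bootstrap parameters.  Binary
#' and categorical columns are imputed on the continuous scale and rounded to
#' the nearest valid category.
#'
#' @inheritParams fcs_impute
#' @param spec an [imputation_spec()] (method `"jm_norm"`).
#' @return an `imputed_stack`.
#' @export
jm_norm_impute <- function(obs, spec = imputation_spec("jm_norm")) {
  vals <- obs[, setdiff(names(obs), indicator_cols(obs)), drop = FALSE]
  types <- imp_col_types(vals)
  X <- as.matrix(vals)
  n <- nrow(X); p <- ncol(X)
  base_seed <- if (is.null(spec$seed)) sample.int(1e6, 1) else spec$seed
  anymiss <- anyNA(X)
  datasets <- vector("list", spec$m)
  for (im in seq_len(spec$m)) {
    set.seed(derive_seed(base_seed, im, "emb"))
    filled <- X
    if (anymiss) {
      em <- NULL
      for (try in 1:3) {
        bs <- X[sample.int(n, n, replace = TRUE), , drop = FALSE]
        # every column must keep observed values in the bootstrap
        if (any(colSums(!is.na(bs)) < 2)) next
        em <- em_mvnorm(bs)
        if (em$converged) break
      }
      if (is.null(em)) stop("EM failed: bootstrap lost all observed values")
      if (!em$converged) stop("EM did not converge after 3 restarts")
      for (i in which(rowSums(is.na(X)) > 0)) {
        misv <- which(is.na(X[i, ]))
        obsv <- setdiff(seq_len(p), misv)
        if (length(obsv)) {
          Sooi <- chol2inv(chol(em$sigma[obsv, obsv, drop = FALSE]))
          Bm <- em$sigma[misv, obsv, drop = FALSE] %*% Sooi
          cmu <- em$mu[misv] + drop(Bm %*% (X[i, obsv] - em$mu[obsv]))
          cS <- em$sigma[misv, misv, drop = FALSE] -
            Bm %*% em$sigma[obsv, misv, drop = FALSE]
        } else {
          cmu <- em$mu[misv]
          cS <- em$sigma[misv, misv, drop = FALSE]
        }
        cS <- (cS + t(cS)) / 2 + diag(1e-10, length(misv))
        filled[i, misv] <- drop(MASS::mvrnorm(1, cmu, cS))
      }
    }
    out <- as.data.frame(filled)
    for (cl in names(out)) {
      if (types[[cl]] == "binary") out[[cl]] <- pmin(pmax(round(out[[cl]]), 0), 1)
      if (types[[cl]] == "categorical")
        out[[cl]] <- pmin(pmax(round(out[[cl]]), 1), 4)
    }
    datasets[[im]] <- out
  }
  structure(list(datasets = datasets, trace = NULL, method = "jm_norm"),
            class = "imputed_stack")
}

#' Pool estimates across imputations by Rubin's rules
#'
#' Total variance is `within + (1 + 1/m) * between`; degrees of freedom by
#' the Barnard-Rubin small-sample formula with complete-data df
#' `n_used - 2`; the 95% interval uses the t distribution on those df.
#'
#' @param estimates vector of per-imputation point estimates.
#' @param variances vector of per-imputation squared standard errors.
#' @param n_used complete-data sample size (for the Barnard-Rubin df).
#' @return object of class `pooled_estimate` with `qbar`, `within`,
#'   `between`, `total_var`, `df`, `ci`, `m`.
#' @export
rubin_pool <- function(estimates, variances, n_used = Inf) {
  m <- length(estimates)
  if (m < 2) stop("Rubin pooling needs at least 2 imputations")
  qbar <- mean(estimates)
  within <- mean(variances)
  between <- var(estimates)
  total <- within + (1 + 1 / m) * between
  lambda <- max((1 + 1 / m) * between / total, 1e-12)
  df_old <- (m - 1) / lambda^2
  dfcom <- if (is.finite(n_used)) max(n_used - 2, 1) else Inf
  df <- if (is.finite(dfcom)) {
    df_obs <- (dfcom + 1) / (dfcom + 3) * dfcom * (1 - lambda)
    df_old * df_obs / (df_old + df_obs)
  } else df_old
  ci <- qbar + c(-1, 1) * qt(0.975, df) * sqrt(total)
  structure(list(qbar = qbar, within = within, between = between,
                 total_var = total, df = df, ci = ci, m = m),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("pooled: %.4f (total var %.5f = %.5f within + %.5f between), m = %d\n",
              x$qbar, x$total_var, x$within, x$between, x$m))
  invisible(x)
}

#' Impute, analyze each completed dataset with TMLE, and pool
#'
#' @param obs ObservedData.
#' @param imspec an [imputation_spec()].
#' @param slspec an [sl_spec()] for the per-dataset TMLE.
#' @return an `ate_estimate` carrying the pooled result (the
#'   `pooled_estimate` object is attached as `$pooled`).
#' @export
mi_analyze <- function(obs, imspec = imputation_spec("pmm"), slspec = sl_spec()) {
  stack <- if (imspec$method == "jm_norm") jm_norm_impute(obs, imspec)
           else fcs_impute(obs, imspec)
  ests <- numeric(0); vars <- numeric(0)
  for (d in stack$datasets) {
    d$A <- round(d$A) # imputed exposure must be binary for TMLE
    d$A <- pmin(pmax(d$A, 0), 1)
    fit <- tmle_ate(d, slspec)
    ests <- c(ests, fit$ate)
    vars <- c(vars, fit$se^2)
  }
  pooled <- rubin_pool(ests, vars, n_used = nrow(obs))
  res <- ate_result(pooled$qbar, sqrt(pooled$total_var), c(NA, NA),
                    nrow(obs), paste0("mi_", stack$method))
  res$ci <- pooled$ci
  res$pooled <- pooled
  res
}
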