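#' Zero-order spline (indicator) basis for the highly adaptive lasso
#'
#' For every nonempty covariate subset `s` with `|s| <= max_degree`, one
#' basis function `phi(w) = prod_{j in s} I(w_j >= knot_j)` is created per
#' knot combination.  Knots sit at distinct observed values; for continuous
#' covariates the knot inventory can be thinned to `num_knots` quantiles
#' (degree 1) and `num_knots2` quantiles (inside interactions) to keep the
#' design manageable.  Constant and exact-duplicate basis columns are
#' collapsed.
#'
#' @param X numeric covariate data.frame or matrix.
#' @param max_degree maximum interaction degree (default 2).
#' @param num_knots,num_knots2 knot caps for degree-1 and degree-2+ bases.
#' @return object of class `hal_basis`: list of `list(vars, knots)` with the
#'   knot inventory attached.
#' @export
make_hal_basis <- function(X, max_degree = 2, num_knots = 25, num_knots2 = 10) {
  X <- as.matrix(X)
  if (!nrow(X) || !ncol(X)) stop("empty covariate table")
  p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(p))
  knot_list <- function(x, cap) {
    u <- sort(unique(x))
    if (length(u) > 1) u <- u[-1] # I(x >= min) is constant
    if (length(u) > cap)
      u <- unique(quantile(x, probs = seq_len(cap) / (cap + 1), type = 1))
    u
  }
  basis <- list()
  for (deg in seq_len(min(max_degree, p))) {
    cap <- if (deg == 1) num_knots else num_knots2
    for (cs in utils::combn(p, deg, simplify = FALSE)) {
      ks <- lapply(cs, function(j) knot_list(X[, j], cap))
      if (any(!lengths(ks))) next
      grid <- expand.grid(ks, KEEP.OUT.ATTRS = FALSE)
      for (r in seq_len(nrow(grid)))
        basis[[length(basis) + 1]] <- list(vars = colnames(X)[cs],
                                           knots = as.numeric(grid[r, ]))
    }
  }
  structure(basis, class = "hal_basis", colnames = colnames(X))
}

#' Evaluate a HAL basis as a sparse design matrix
#'
#' @param basis a [make_hal_basis()] object.
#' @param X covariate table with the columns the basis was built on.
#' @param dedupe drop constant and duplicate columns (records the kept index).
#' @return sparse matrix (`dgCMatrix`) with one column per retained basis.
#' @export
hal_design <- function(basis, X, dedupe = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X)
  cols <- vector("list", length(basis))
  for (b in seq_along(basis)) {
    bb <- basis[[b]]
    v <- rep(TRUE, n)
    for (j in seq_along(bb$vars))
      v <- v & (X[, bb$vars[j]] >= bb$knots[j])
    cols[[b]] <- which(v)
  }
  M <- Matrix::sparseMatrix(
    i = unlist(cols),
    j = rep(seq_along(cols), lengths(cols)),
    x = 1, dims = c(n, length(basis)))
  if (!dedupe) return(M)
  keep <- !duplicated(lapply(cols, identity)) & lengths(cols) > 0 &
    lengths(cols) < n
  list(design = M[, keep, drop = FALSE], keep = which(keep))
}

# L1 norms (excluding intercept) along a glmnet path
path_l1 <- function(fit) colSums(abs(as.matrix(fit$beta)))

# glmnet needs >= 2 columns; an all-zero pad column never enters the model
pad_design <- function(D) if (ncol(D) < 2) cbind(D, 0) else D

hal_predict_raw <- function(fit, X) {
  D <- hal_design(fit$basis, X)[, fit$keep, drop = FALSE]
  lp <- as.numeric(D %*% fit$beta) + fit$beta0
  if (fit$loss == "logistic") plogis(lp) else lp
}

#' Fit HAL at a given L1-norm bound
#'
#' Empirical-risk minimization over the indicator-basis expansion subject to
#' `sum |beta| <= C`, through the penalized lasso path: the path is fit once
#' and the solution whose coefficient L1 norm is largest while not exceeding
#' `C` is selected (the intercept is outside the bound).
#'
#' @param X covariate table.
#' @param y response (continuous, or 0/1 for `loss = "logistic"`).
#' @param C nonnegative L1 bound; `C = 0` gives the intercept-only model.
#' @param loss `"squared"` or `"logistic"`.
#' @param basis optional precomputed [make_hal_basis()].
#' @param max_degree,num_knots,num_knots2 passed to [make_hal_basis()].
#' @return object of class `hal_fit` with `beta0`, `beta` (retained basis
#'   coefficients), `C`, `l1`, `sigma2` (residual variance, squared loss) and
#'   a `$predict(newX)` on the response scale.
#' @export
fit_hal <- function(X, y, C, loss = c("squared", "logistic"), basis = NULL,
                    max_degree = 2, num_knots = 25, num_knots2 = 10) {
  loss <- match.arg(loss)
  if (C < 0) stop("C must be nonnegative")
  if (is.null(basis)) basis <- make_hal_basis(X, max_degree, num_knots, num_knots2)
  dd <- hal_design(basis, X, dedupe = TRUE)
  fam <- if (loss == "logistic") "binomial" else "gaussian"
  path <- glmnet::glmnet(pad_design(dd$design), y, family = fam,
                         standardize = FALSE)
  hal_from_path(path, basis, dd$keep, X, y, C, loss)
}

hal_from_path <- function(path, basis, keep, X, y, C, loss) {
  l1 <- path_l1(path)
  ok <- which(l1 <= C + 1e-8)
  fit <- list(basis = basis, keep = keep, loss = loss, C = C, path = path)
  if (length(ok)) {
    j <- ok[which.max(l1[ok])]
    fit$beta <- as.numeric(path$beta[seq_along(keep), j])
    fit$beta0 <- path$a0[j]
    fit$l1 <- l1[j]
  } else {
    fit$beta <- rep(0, length(keep))
    fit$beta0 <- if (loss == "logistic") qlogis(pmin(pmax(mean(y), 1e-6), 1 - 1e-6))
                 else mean(y)
    fit$l1 <- 0
  }
  pred <- hal_predict_raw(fit, X)
  fit$sigma2 <- if (loss == "squared") mean((y - pred)^2) else NA_real_
  fit$predict <- function(newX) hal_predict_raw(fit, newX)
  class(fit) <- "hal_fit"
  fit
}

#' @export
predict.hal_fit <- function(object, newdata, ...) hal_predict_raw(object, newdata)

#' Select the HAL L1 bound by cross-validation
#'
#' Runs `cv.glmnet` over the basis expansion and returns the cross-validated
#' bound `Ccv` (the L1 norm at the CV-risk-minimizing penalty) together with
#' the corresponding fit.
#'
#' @inheritParams fit_hal
#' @param folds number of CV folds.
#' @param seed optional integer seed (fold assignment).
#' @return list with `Ccv`, `cv_fit` (a `hal_fit`), `basis`, `keep`.
#' @export
cv_select_C <- function(X, y, loss = c("squared", "logistic"), folds = 5,
                        basis = NULL, seed = NULL,
                        max_degree = 2, num_knots = 25, num_knots2 = 10) {
  loss <- match.arg(loss)
  if (is.null(basis)) basis <- make_hal_basis(X, max_degree, num_knots, num_knots2)
  dd <- hal_design(basis, X, dedupe = TRUE)
  fam <- if (loss == "logistic") "binomial" else "gaussian"
  with_seed(seed, {
    cvf <- glmnet::cv.glmnet(pad_design(dd$design), y, family = fam,
                             nfolds = folds, standardize = FALSE)
    j <- which(cvf$lambda == cvf$lambda.min)[1]
    Ccv <- path_l1(cvf$glmnet.fit)[j]
    fit <- hal_from_path(cvf$glmnet.fit, basis, dd$keep, X, y, Ccv, loss)
    fit$Ccv <- Ccv
    list(Ccv = Ccv, cv_fit = fit, basis = basis, keep = dd$keep)
  })
}

#' Undersmooth a cross-validated HAL fit
#'
#' Starting from the CV bound, the L1 bound is multiplied by 1.2 per step and
#' the model refit until, for every basis function retained in the initial CV
#' fit, the empirical score `|Pn(phi * (y - Qbar))|` is no larger than its
#' bound `sigma_n / (sqrt(n) * log(n))`, with `sigma_n` the standard
#' deviation of `phi * (y - Qbar_cv)` fixed at the CV fit.  Stops after 50
#' steps if the criterion is not met (flagged).
#'
#' @param X,y training data.
#' @param cv_selection result of [cv_select_C()].
#' @return a `hal_fit` with fields `undersmoothed` (criterion met),
#'   `C`, and `steps`.
#' @export
undersmooth <- function(X, y, cv_selection) {
  cvfit <- cv_selection$cv_fit
  basis <- cv_selection$basis
  n <- length(y)
  D <- hal_design(basis, X)[, cvfit$keep, drop = FALSE]
  active <- which(cvfit$beta != 0)
  pred_cv <- hal_predict_raw(cvfit, X)
  res_cv <- y - pred_cv
  if (!length(active)) { # CV picked the intercept-only model: nothing to score
    cvfit$undersmoothed <- TRUE
    cvfit$steps <- 0L
    return(cvfit)
  }
  Phi <- D[, active, drop = FALSE]
  sig <- apply(as.matrix(Phi * res_cv), 2, sd)
  usable <- sig > 1e-12
  bound <- sig / (sqrt(n) * log(n))
  fit <- cvfit
  steps <- 0L
  repeat {
    pred <- hal_predict_raw(fit, X)
    score <- abs(colMeans(as.matrix(Phi * (y - pred))))
    met <- all(score[usable] <= bound[usable])
    if (met || steps >= 50) {
      fit$undersmoothed <- met
      fit$steps <- steps
      fit$score_max <- max(score[usable] / bound[usable])
      return(fit)
    }
    steps <- steps + 1L
    Cnew <- cvfit$Ccv * 1.2^steps
    fit <- hal_from_path(cvfit$path, basis, cvfit$keep, X, y, Cnew, cvfit$loss)
    fit$Ccv <- cvfit$Ccv
  }
}

#' Generate synthetic data from fitted HAL conditionals
#'
#' Resamples covariate rows from a pool, draws the exposure from the fitted
#' propensity HAL (probabilities clipped to `[1e-4, 1 - 1e-4]`), and draws
#' the outcome as the fitted conditional mean at the sampled `(A, W)` plus
#' `Normal(0, sigma2)` noise with the fit's residual variance.
#'
#' @param fitA logistic-loss `hal_fit` of `A` on `W`.
#' @param fitY squared-loss `hal_fit` of `Y` on `(A, W)` (exposure column
#'   named `A`).
#' @param W_pool covariate pool data.frame.
#' @param n rows to generate.
#' @param seed optional integer seed.
#' @return data.frame with the pool's columns plus `A` and `Y`.
#' @export
design_based_generate <- function(fitA, fitY, W_pool, n, seed = NULL) {
  with_seed(seed, {
    W <- W_pool[sample.int(nrow(W_pool), n, replace = TRUE), , drop = FALSE]
    pa <- pmin(pmax(hal_predict_raw(fitA, W), 1e-4), 1 - 1e-4)
    A <- rbinom(n, 1, pa)
    XY <- cbind(A = A, W)
    mu <- hal_predict_raw(fitY, XY)
    Y <- mu + rnorm(n, 0, sqrt(fitY$sigma2))
    out <- cbind(W, A = A, Y = Y)
    rownames(out) <- NULL
    out
  })
}

#' Quasi-true ATE of a fitted HAL outcome model over a covariate pool
#'
#' Resamples `N` rows from the pool and averages the predicted contrast
#' between the two exposure arms.
#'
#' @inheritParams design_based_generate
#' @param N number of resampled rows (the study uses 250,000).
#' @return the average predicted treatment contrast.
#' @export
quasi_true_ate <- function(fitY, W_pool, N = 250000, seed = NULL) {
  with_seed(seed, {
    W <- W_pool[sample.int(nrow(W_pool), N, replace = TRUE), , drop = FALSE]
    mean(hal_predict_raw(fitY, cbind(A = 1, W)) -
           hal_predict_raw(fitY, cbind(A = 0, W)))
  })
}
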