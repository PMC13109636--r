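#' Super Learner specification
#'
#' The default library follows the analysis layer's design: a main-effects
#' GLM, a GLM with all two-way interactions, a restricted-cubic-spline GLM
#' standing in as the adaptive-spline learner, and the arithmetic mean.
#'
#' @param learners character vector from `c("glm", "glm_int", "rcs", "mean")`.
#' @param folds number of cross-validation folds (>= 2).
#' @param seed optional integer seed for fold assignment.
#' @return object of class `sl_spec`.
#' @export
sl_spec <- function(learners = c("glm", "glm_int", "rcs", "mean"),
                    folds = 10, seed = NULL) {
  stopifnot(length(learners) >= 1, folds >= 2)
  unknown <- setdiff(learners, c("glm", "glm_int", "rcs", "mean"))
  if (length(unknown)) stop("unknown learners: ", paste(unknown, collapse = ", "))
  structure(list(learners = learners, folds = as.integer(folds), seed = seed),
            class = "sl_spec")
}

# ---- base learners -----------------------------------------------------------
# each learner: fit(X, y, family) -> object with predict(newX) on the
# response scale.  X is a data.frame of numeric columns without missing cells.

sl_design <- function(X, kind, ns_bases = NULL) {
  M <- as.matrix(X)
  if (kind == "glm") return(cbind(`(Intercept)` = 1, M))
  if (kind == "glm_int") {
    p <- ncol(M)
    ints <- list()
    if (p >= 2) for (i in 1:(p - 1)) for (j in (i + 1):p)
      ints[[paste0(colnames(M)[i], ":", colnames(M)[j])]] <- M[, i] * M[, j]
    return(cbind(`(Intercept)` = 1, M,
                 if (length(ints)) do.call(cbind, ints)))
  }
  if (kind == "rcs") {
    cols <- list(`(Intercept)` = rep(1, nrow(M)))
    for (j in seq_len(ncol(M))) {
      nm <- colnames(M)[j]
      if (!is.null(ns_bases[[nm]])) {
        bs <- predict(ns_bases[[nm]], M[, j])
        colnames(bs) <- paste0(nm, ".ns", seq_len(ncol(bs)))
        cols[[nm]] <- bs
      } else cols[[nm]] <- M[, j, drop = FALSE]
    }
    return(do.call(cbind, cols))
  }
  stop("unknown design kind")
}

fit_one_learner <- function(kind, X, y, family) {
  if (kind == "mean") {
    mu <- mean(y)
    return(list(kind = "mean", mu = mu))
  }
  ns_bases <- NULL
  if (kind == "rcs") {
    ns_bases <- list()
    for (nm in names(X)) {
      x <- X[[nm]]
      if (length(unique(x)) >= 10) # continuous: natural cubic spline, 4 df
        ns_bases[[nm]] <- splines::ns(x, df = 4)
    }
  }
  D <- sl_design(X, kind, ns_bases)
  keep <- qr(D)$pivot[seq_len(qr(D)$rank)] # guard against rank deficiency
  Dk <- D[, sort(keep), drop = FALSE]
  if (family == "binomial") {
    f <- suppressWarnings(glm.fit(Dk, y, family = binomial()))
    beta <- f$coefficients
  } else {
    f <- lm.fit(Dk, y)
    beta <- f$coefficients
  }
  beta[is.na(beta)] <- 0
  list(kind = kind, beta = beta, cols = colnames(Dk), ns_bases = ns_bases,
       family = family)
}

predict_one_learner <- function(fit, newX) {
  if (fit$kind == "mean") return(rep(fit$mu, nrow(newX)))
  D <- sl_design(newX, fit$kind, fit$ns_bases)
  lp <- drop(D[, fit$cols, drop = FALSE] %*% fit$beta)
  if (fit$family == "binomial") plogis(lp) else lp
}

# tiny active-set non-negative least squares (library sizes are <= 4)
nnls_weights <- function(Z, y) {
  L <- ncol(Z)
  act <- seq_len(L)
  coefs <- rep(0, L)
  repeat {
    Za <- Z[, act, drop = FALSE]
    b <- tryCatch(solve(crossprod(Za) + diag(1e-10, length(act)),
                        crossprod(Za, y)),
                  error = function(e) NULL)
    if (is.null(b)) { coefs[act] <- 1 / length(act); break }
    b <- drop(b)
    if (all(b >= -1e-10)) { coefs[act] <- pmax(b, 0); break }
    act <- act[-which.min(b)]
    if (!length(act)) break
  }
  if (sum(coefs) <= 0) { # degenerate: fall back to the single best CV learner
    risks <- colMeans((Z - y)^2)
    coefs[which.min(risks)] <- 1
  }
  coefs / sum(coefs)
}

make_folds <- function(n, folds, strata = NULL) {
  if (is.null(strata)) return(sample(rep(seq_len(folds), length.out = n)))
  id <- integer(n)
  for (s in unique(strata)) {
    ix <- which(strata == s)
    id[ix] <- sample(rep(seq_len(folds), length.out = length(ix)))
  }
  id
}

#' Fit a cross-validated Super Learner ensemble
#'
#' V-fold cross-validated predictions are computed for every base learner;
#' convex weights (nonnegative, summing to one) minimizing the cross-validated
#' squared-error loss are found by constrained least squares; the final
#' predictor is the weighted combination of the learners refit on the full
#' data.  With a single learner the CV step is skipped and the learner gets
#' weight one.  Predictions for probability targets are clipped to
#' `[1e-6, 1 - 1e-6]`.
#'
#' @param X data.frame of predictors (no missing cells).
#' @param y response vector (binary 0/1 for `family = "binomial"`).
#' @param spec an [sl_spec()].
#' @param family `"gaussian"` or `"binomial"`.
#' @param strata optional stratification vector for fold assignment.
#' @return object of class `sl_fit` with elements `weights`, `fits`,
#'   `cv_risk`, and a `$predict(newX)` closure.
#' @export
fit_super_learner <- function(X, y, spec = sl_spec(), family = "gaussian",
                              strata = NULL) {
  stopifnot(is.data.frame(X), nrow(X) == length(y), !anyNA(X), !anyNA(y))
  learners <- spec$learners
  L <- length(learners)
  n <- nrow(X)
  folds <- min(spec$folds, n)
  if (family == "binomial") {
    ncls <- min(table(y))
    if (ncls < folds && length(unique(y)) > 1) {
      folds <- max(2L, as.integer(ncls))
      warning("reduced folds to ", folds, " (sparse class)")
    }
    if (is.null(strata)) strata <- y
  }
  with_seed(spec$seed, {
    weights <- rep(0, L)
    names(weights) <- learners
    cv_risk <- rep(NA_real_, L)
    names(cv_risk) <- learners
    if (L == 1) {
      weights[1] <- 1
    } else {
      fold_id <- make_folds(n, folds, strata)
      Z <- matrix(NA_real_, n, L)
      for (v in seq_len(folds)) {
        tr <- fold_id != v
        for (l in seq_len(L)) {
          f <- fit_one_learner(learners[l], X[tr, , drop = FALSE], y[tr], family)
          Z[!tr, l] <- predict_one_learner(f, X[!tr, , drop = FALSE])
        }
      }
      if (family == "binomial") Z <- pmin(pmax(Z, 1e-6), 1 - 1e-6)
      cv_risk <- setNames(colMeans((Z - y)^2), learners)
      weights <- setNames(nnls_weights(Z, y), learners)
    }
    fits <- lapply(learners, function(l) fit_one_learner(l, X, y, family))
    pred_fun <- function(newX) {
      P <- vapply(fits, predict_one_learner, numeric(nrow(newX)), newX = newX)
      if (is.null(dim(P))) P <- matrix(P, nrow = 1)
      out <- drop(P %*% weights)
      if (family == "binomial") out <- pmin(pmax(out, 1e-6), 1 - 1e-6)
      out
    }
    structure(list(weights = weights, fits = fits, cv_risk = cv_risk,
                   family = family, predict = pred_fun),
              class = "sl_fit")
  })
}

#' @export
predict.sl_fit <- function(object, newdata, ...) object$predict(newdata)
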