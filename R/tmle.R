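#' Scale a continuous outcome to the unit interval
#'
#' @param y numeric vector with `max(y) > min(y)`.
#' @return list with `y01` (the rescaled outcome) and `bounds = c(min, max)`;
#'   multiply estimates and standard errors by `diff(bounds)` to return to the
#'   original scale.
#' @export
scale_outcome <- function(y) {
  b <- range(y)
  if (diff(b) <= 0) stop("constant outcome cannot be scaled")
  list(y01 = (y - b[1]) / diff(b), bounds = b)
}

#' Truncate propensity scores to [0.01, 0.99]
#'
#' Estimated scores below 0.01 are set to 0.01 (and symmetrically above 0.99),
#' stabilizing the clever covariates under near-positivity violations.
#'
#' @param g vector of probabilities.
#' @param lower lower bound (default 0.01); upper bound is `1 - lower`.
#' @return truncated vector.
#' @export
truncate_ps <- function(g, lower = 0.01) pmin(pmax(g, lower), 1 - lower)

#' Clever covariates for the targeting step
#'
#' @param A binary exposure vector.
#' @param g truncated propensity scores `P(A=1|W)`.
#' @return list with `H1 = I(A=1)/g`, `H0 = I(A=0)/(1-g)` and the signed
#'   observed-exposure covariate `H_at_A = H1 - H0` used in the influence
#'   curve.
#' @export
clever_covariates <- function(A, g) {
  H1 <- A / g
  H0 <- (1 - A) / (1 - g)
  list(H1 = H1, H0 = H0, H_at_A = H1 - H0)
}

#' Fluctuation (targeting) step
#'
#' Fits the intercept-free two-parameter logistic fluctuation with
#' `logit(Q)` as offset and the two clever covariates as predictors, on the
#' records selected by `fit_mask`, then updates both counterfactual
#' predictions.  With outcome-missingness weights (`r1`, `r0`, `obs`), the
#' clever covariates gain the joint inverse weight
#' `I(M_Y = 0) / r(M_Y = 0 | A, W)`.
#'
#' @param Q0,Q1 initial predictions (in (0,1)) at `A = 0` and `A = 1`.
#' @param y01 scaled outcome (may be NA where `obs` is FALSE).
#' @param A binary exposure.
#' @param g truncated propensity scores.
#' @param fit_mask logical records contributing to the fluctuation fit
#'   (default: all records with an observed outcome).
#' @param r1,r0 optional truncated outcome-observation probabilities
#'   `P(M_Y=0 | A=1, W)` and `P(M_Y=0 | A=0, W)` (default 1).
#' @param obs logical vector, TRUE where the outcome is observed.
#' @return list with `Qstar0`, `Qstar1`, `eps` (length 2) and the per-record
#'   fluctuation covariates `H1`, `H0` evaluated at the observed exposure.
#' @export
fluctuate <- function(Q0, Q1, y01, A, g, fit_mask = NULL, r1 = NULL, r0 = NULL,
                      obs = NULL) {
  n <- length(A)
  if (is.null(r1)) r1 <- rep(1, n)
  if (is.null(r0)) r0 <- rep(1, n)
  if (is.null(obs)) obs <- rep(TRUE, n)
  if (is.null(fit_mask)) fit_mask <- obs
  QA <- ifelse(A == 1, Q1, Q0)
  H1 <- A * obs / (g * r1)
  H0 <- (1 - A) * obs / ((1 - g) * r0)
  eps <- c(0, 0)
  fit <- tryCatch(
    suppressWarnings(glm.fit(cbind(H1, H0)[fit_mask, , drop = FALSE],
                             y01[fit_mask],
                             family = quasibinomial(),
                             offset = qlogis(QA[fit_mask]),
                             control = list(epsilon = 1e-12, maxit = 100))),
    error = function(e) NULL)
  if (!is.null(fit) && fit$converged && !anyNA(fit$coefficients)) {
    eps <- fit$coefficients
  } else {
    warning("fluctuation did not converge; keeping the initial plug-in")
  }
  Qstar1 <- plogis(qlogis(Q1) + eps[1] / (g * r1))
  Qstar0 <- plogis(qlogis(Q0) + eps[2] / ((1 - g) * r0))
  list(Qstar0 = Qstar0, Qstar1 = Qstar1, eps = unname(eps), H1 = H1, H0 = H0)
}

bound01 <- function(p, eps = 1e-6) pmin(pmax(p, eps), 1 - eps)

ate_result <- function(ate, se, eps, n_used, method) {
  ci <- ate + c(-1, 1) * 1.96 * se
  structure(list(ate = ate, se = se, ci = ci, eps = eps,
                 n_used = n_used, method = method),
            class = "ate_estimate")
}

#' @export
print.ate_estimate <- function(x, ...) {
  cat(sprintf("%s: ATE = %.4f (SE %.4f), 95%% CI [%.4f, %.4f], n = %d\n",
              x$method, x$ate, x$se, x$ci[1], x$ci[2], x$n_used))
  invisible(x)
}

analysis_covariates <- function(data) {
  setdiff(names(data), c("A", "Y", "B", grep("^M_", names(data), value = TRUE)))
}

# numeric analysis frame: the four-category confounder enters as dummies
analysis_frame <- function(data, covariates) {
  X <- data[, covariates, drop = FALSE]
  if ("W3" %in% names(X) && length(unique(na.omit(data$W3))) > 2 &&
      all(na.omit(data$W3) %in% 1:4)) {
    X$W3_2 <- as.numeric(X$W3 == 2)
    X$W3_3 <- as.numeric(X$W3 == 3)
    X$W3_4 <- as.numeric(X$W3 == 4)
    X$W3 <- NULL
  }
  X
}

#' TMLE of the average treatment effect on complete records
#'
#' Pipeline: scale the outcome to `[0,1]`; fit the outcome regression
#' `Q(A, W)` and the propensity score `g(1|W)` by Super Learner; truncate `g`
#' to `[0.01, 0.99]`; target via the two-parameter fluctuation; average the
#' updated counterfactual predictions; variance from the efficient influence
#' curve.
#'
#' @param data data.frame with columns `A`, `Y`, confounders (and optionally
#'   `B`, which is not adjusted for), no missing cells among used columns.
#' @param slspec an [sl_spec()].
#' @param covariates adjustment set (default: every column except `A`, `Y`,
#'   `B` and indicator columns).
#' @return an `ate_estimate`.
#' @export
tmle_ate <- function(data, slspec = sl_spec(), covariates = analysis_covariates(data)) {
  if (length(unique(data$A)) < 2) stop("one exposure arm is empty")
  W <- analysis_frame(data, covariates)
  stopifnot(!anyNA(W), !anyNA(data$A), !anyNA(data$Y))
  n <- nrow(data)
  sc <- scale_outcome(data$Y)
  y01 <- sc$y01
  XQ <- cbind(A = data$A, W)
  fQ <- fit_super_learner(XQ, y01, slspec, family = "gaussian")
  Q1 <- bound01(fQ$predict(cbind(A = rep(1, n), W)))
  Q0 <- bound01(fQ$predict(cbind(A = rep(0, n), W)))
  fg <- fit_super_learner(W, data$A, slspec, family = "binomial")
  g <- truncate_ps(fg$predict(W))
  fl <- fluctuate(Q0, Q1, y01, data$A, g)
  psi01 <- mean(fl$Qstar1 - fl$Qstar0)
  QstarA <- ifelse(data$A == 1, fl$Qstar1, fl$Qstar0)
  ic <- (fl$H1 - fl$H0) * (y01 - QstarA) + fl$Qstar1 - fl$Qstar0 - psi01
  rng <- diff(sc$bounds)
  ate_result(psi01 * rng, sqrt(var(ic) / n) * rng, fl$eps, n, "tmle")
}

#' Extended TMLE with an outcome-missingness model
#'
#' For records complete in `(A, W)` but with possibly missing outcomes, the
#' targeting step incorporates an outcome-observation model: the clever
#' covariate becomes `I(A=a) I(M_Y=0) / (g(a|W) r(M_Y=0|a, W))` with `r`
#' estimated by Super Learner and truncated at 0.01.  The outcome regression
#' and the fluctuation use the observed-outcome records; the updated
#' predictions are averaged over all input records.  With zero outcome
#' missingness this reduces exactly to [tmle_ate()].
#'
#' @param data data.frame with `A`, `Y` (NA where missing), `M_Y` indicator,
#'   and complete confounders.
#' @inheritParams tmle_ate
#' @return an `ate_estimate`.
#' @export
tmle_ext <- function(data, slspec = sl_spec(), covariates = analysis_covariates(data)) {
  if (!"M_Y" %in% names(data)) stop("tmle_ext needs the M_Y indicator column")
  obs <- data$M_Y == 0
  if (!any(obs & data$A == 1) || !any(obs & data$A == 0))
    stop("no observed outcomes in one exposure arm")
  if (all(obs)) {
    res <- tmle_ate(data[, setdiff(names(data), "M_Y")], slspec, covariates)
    res$method <- "tmle_ext"
    return(res)
  }
  W <- analysis_frame(data, covariates)
  stopifnot(!anyNA(W), !anyNA(data$A))
  n <- nrow(data)
  sc <- scale_outcome(data$Y[obs])
  y01 <- rep(NA_real_, n)
  y01[obs] <- sc$y01
  XQ <- cbind(A = data$A, W)
  fQ <- fit_super_learner(XQ[obs, , drop = FALSE], y01[obs], slspec,
                          family = "gaussian")
  Q1 <- bound01(fQ$predict(cbind(A = rep(1, n), W)))
  Q0 <- bound01(fQ$predict(cbind(A = rep(0, n), W)))
  fg <- fit_super_learner(W, data$A, slspec, family = "binomial")
  g <- truncate_ps(fg$predict(W))
  fr <- fit_super_learner(XQ, as.numeric(obs), slspec, family = "binomial",
                          strata = as.numeric(obs))
  r1 <- truncate_ps(fr$predict(cbind(A = rep(1, n), W)))
  r0 <- truncate_ps(fr$predict(cbind(A = rep(0, n), W)))
  fl <- fluctuate(Q0, Q1, y01, data$A, g, fit_mask = obs, r1 = r1, r0 = r0,
                  obs = obs)
  psi01 <- mean(fl$Qstar1 - fl$Qstar0)
  QstarA <- ifelse(data$A == 1, fl$Qstar1, fl$Qstar0)
  resid <- ifelse(obs, y01 - QstarA, 0)
  ic <- (fl$H1 - fl$H0) * resid + fl$Qstar1 - fl$Qstar0 - psi01
  rng <- diff(sc$bounds)
  ate_result(psi01 * rng, sqrt(var(ic) / n) * rng, fl$eps, n, "tmle_ext")
}

# ---- dataset strategies ------------------------------------------------------

indicator_cols <- function(obs) grep("^M_", names(obs), value = TRUE)

#' Complete-case analysis table
#'
#' Drops every record with any missing value among confounders, exposure or
#' outcome, and removes the indicator columns.
#'
#' @param obs ObservedData from [apply_missingness()].
#' @return analysis table for [tmle_ate()].
#' @export
prepare_cc <- function(obs) {
  ind <- indicator_cols(obs)
  keep <- rowSums(obs[, ind, drop = FALSE]) == 0
  obs[keep, setdiff(names(obs), ind), drop = FALSE]
}

#' Extended-TMLE analysis table
#'
#' Drops records missing any confounder or the exposure; keeps records with
#' missing outcomes together with the `M_Y` indicator for [tmle_ext()].
#'
#' @inheritParams prepare_cc
#' @return analysis table with `M_Y` retained.
#' @export
prepare_ext <- function(obs) {
  ind <- setdiff(indicator_cols(obs), "M_Y")
  keep <- rowSums(obs[, ind, drop = FALSE]) == 0
  obs[keep, setdiff(names(obs), ind), drop = FALSE]
}

#' Extended-TMLE + missing covariate missing indicator table
#'
#' Drops only records with missing exposure.  Each incomplete confounder is
#' filled with a reference constant (0 / category 1 for binary and
#' categorical, the observed mean for continuous) and its missingness
#' indicator is kept as an additional covariate.  `M_Y` is retained for
#' [tmle_ext()].
#'
#' @inheritParams prepare_cc
#' @return analysis table with filled confounders and indicator covariates.
#' @export
prepare_ext_mcmi <- function(obs) {
  out <- obs[obs$M_A == 0, , drop = FALSE]
  wind <- setdiff(indicator_cols(out), c("M_A", "M_Y"))
  for (mn in wind) {
    v <- sub("^M_", "", mn)
    mis <- out[[mn]] == 1
    if (!any(mis)) next
    vals <- out[[v]][!mis]
    fill <- if (all(vals %in% 0:1)) 0
            else if (all(vals %in% 1:4) && length(unique(vals)) <= 4) 1
            else mean(vals)
    out[[v]][mis] <- fill
  }
  out$M_A <- NULL
  out
}
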