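#' Build the missingness specification for one m-DAG
#'
#' Encodes which substantive variables parent each missingness indicator under
#' mechanisms A-E, together with the coefficient conventions: 0.6 for binary
#' parents, 0.2 for standardized continuous parents and the outcome, negative
#' signs for A and W5, positive otherwise.  Direct arrows among the indicators
#' (the chain `M_W2 -> M_W3 -> M_W4 -> (M_W6) -> M_A -> M_Y`) are present in
#' every mechanism and control joint missingness.
#'
#' Mechanisms: **A** (MCAR) has no substantive parents; **B** (MAR) uses only
#' the fully observed `W1, W5`; **C** adds self-masking `V -> M_V` and
#' exposure-driven missingness but no outcome arrows; **D** adds outcome
#' arrows into the confounder and exposure indicators; **E** additionally lets
#' the outcome mask itself (`Y -> M_Y`), matching the full sequential models.
#'
#' @param name m-DAG label `"A"`..`"E"`.
#' @param dgp_id integer 1-5 (DGP 5 inserts `M_W6` between `M_W4` and `M_A`).
#' @param miss list of missingness conventions (see
#'   [default_coefficients()]`$miss`).
#' @return an object of class `mdag_spec`.
#' @export
build_mdag <- function(name, dgp_id = 1, miss = default_coefficients(dgp_id)$miss) {
  if (!name %in% c("A", "B", "C", "D", "E")) stop("unknown m-DAG: ", name)
  vars <- c("W2", "W3", "W4", if (dgp_id == 5) "W6", "A", "Y")

  base_sub <- function(v) switch(name,
    A = character(0),
    B = c("W1", "W5"),
    C = , D = , E = {
      self <- if (v %in% c("W2", "W3", "W4", "W6", "A")) v else character(0)
      rich <- if (v %in% c("A", "Y")) setdiff(vars, c("A", "Y")) else character(0)
      expo <- if (v == "A") character(0) else "A"
      y_in <- if (name == "C") character(0)
              else if (name == "D" && v == "Y") character(0)
              else if (v == "Y" && name == "E") "Y"
              else if (v != "Y" && name %in% c("D", "E")) "Y"
              else character(0)
      unique(c("W1", "W5", self, rich, expo, y_in))
    })

  nodes <- list()
  earlier <- character(0)
  for (v in vars) {
    mnode <- paste0("M_", v)
    sub <- base_sub(v)
    sub_coef <- vapply(sub, miss_parent_coef, numeric(1),
                       dgp_id = dgp_id, miss = miss)
    mcoef <- if (length(earlier)) {
      cc <- rep(switch(v, A = miss$chain_a, Y = miss$chain_ya, miss$chain_w),
                length(earlier))
      names(cc) <- earlier
      if (v == "Y" && "M_A" %in% earlier) cc["M_A"] <- miss$chain_y
      # M_W6 stays out of the A/Y chain so the joint A/Y and Any margins
      # tuned on the core indicators carry over to DGP 5
      if (v %in% c("A", "Y") && "M_W6" %in% earlier) cc["M_W6"] <- 0
      cc
    } else numeric(0)
    nodes[[mnode]] <- list(var = v, mnode = mnode,
                           parents_sub = sub_coef, parents_m = mcoef,
                           target = unname(miss$targets[v]),
                           intercept = NA_real_)
    earlier <- c(earlier, mnode)
  }
  structure(list(name = name, dgp_id = dgp_id, nodes = nodes), class = "mdag_spec")
}

miss_parent_coef <- function(var, dgp_id, miss) {
  sgn <- if (var %in% c("A", "W5")) -1 else 1
  binary <- switch(var,
    W1 = , W2 = , W3 = , A = TRUE,
    W4 = dgp_id == 1, W5 = dgp_id == 1,
    W6 = FALSE, Y = FALSE)
  sgn * if (binary) miss$coef_bin else miss$coef_cont
}

#' @export
print.mdag_spec <- function(x, ...) {
  cat(sprintf("m-DAG %s (DGP %d)\n", x$name, x$dgp_id))
  for (nd in x$nodes)
    cat(sprintf("  %s <- {%s} + {%s}, target %.2f\n", nd$mnode,
                paste(names(nd$parents_sub), collapse = ","),
                paste(names(nd$parents_m), collapse = ","), nd$target))
  invisible(x)
}

#' Standardize continuous columns with the population (divisor n) convention
#'
#' Used on continuous parents before they enter a missingness linear
#' predictor, so that a coefficient of 0.2 moves the log-odds by 0.4 between
#' one in-sample SD below and above the mean, exactly.
#'
#' @param data data.frame.
#' @param columns names of continuous columns to standardize.
#' @return `data` with those columns centered and scaled (others untouched).
#' @export
standardize_continuous_parents <- function(data, columns) {
  for (cl in columns) {
    x <- data[[cl]]
    mu <- mean(x)
    s <- sqrt(mean((x - mu)^2))
    if (s < 1e-12) stop("zero-variance column: ", cl)
    data[[cl]] <- (x - mu) / s
  }
  data
}

miss_continuous_columns <- function(dgp_id) {
  c(if (dgp_id >= 2) c("W4", "W5"), if (dgp_id == 5) "W6", "Y")
}

# linear predictor of one missingness node, excluding the intercept
miss_node_lp <- function(node, data_std, dgp_id, M) {
  lp <- numeric(nrow(data_std))
  for (v in names(node$parents_sub)) {
    x <- if (v == "W3") w3_binary(data_std, dgp_id) else data_std[[v]]
    lp <- lp + node$parents_sub[[v]] * x
  }
  for (mn in names(node$parents_m)) lp <- lp + node$parents_m[[mn]] * M[[mn]]
  lp
}

#' Calibrate the missingness intercepts sequentially on a large sample
#'
#' Walks the indicator chain in order; for each node, solves the intercept so
#' the node's marginal rate equals its target given the substantive parents
#' and the already-drawn earlier indicators, then draws the indicator and
#' moves on.  Intercepts are frozen afterwards for all replicates.
#'
#' @param data complete calibration dataset.
#' @param spec an [build_mdag()] specification.
#' @param seed optional integer seed for the sequential draws.
#' @return named vector of intercepts, one per missingness node.
#' @export
calibrate_mdag_intercepts <- function(data, spec, seed = NULL) {
  std <- standardize_continuous_parents(data, miss_continuous_columns(spec$dgp_id))
  with_seed(seed, {
    M <- list()
    ic <- numeric(0)
    for (nd in spec$nodes) {
      lp <- miss_node_lp(nd, std, spec$dgp_id, M)
      c0 <- calibrate_intercept(nd$target, lp)
      ic[nd$mnode] <- c0
      M[[nd$mnode]] <- rbinom(nrow(data), 1, plogis(c0 + lp))
    }
    ic
  })
}

#' Impose m-DAG missingness on a complete dataset
#'
#' Draws the indicators sequentially in the fixed order, each conditioning on
#' its substantive parents (continuous ones standardized in-sample) and on
#' previously drawn indicators, then masks the corresponding cells with `NA`.
#' `B`, `W1` and `W5` remain fully observed.
#'
#' @param data complete dataset from [generate_complete_data()].
#' @param spec an [build_mdag()] specification.
#' @param seed optional integer seed.
#' @param intercepts named intercept vector from
#'   [calibrate_mdag_intercepts()]; if `NULL`, intercepts are calibrated on
#'   `data` itself (convenient for one-off draws, but replicate studies should
#'   freeze them via [calibrate_scenario()]).
#' @return data.frame with the original columns (masked where missing) plus
#'   indicator columns `M_W2, ..., M_A, M_Y` (1 = missing).
#' @export
apply_missingness <- function(data, spec, seed = NULL, intercepts = NULL) {
  for (nd in spec$nodes)
    if (!nd$var %in% names(data))
      stop("data lacks column ", nd$var, " required by the m-DAG for this DGP")
  if (is.null(intercepts))
    intercepts <- calibrate_mdag_intercepts(data, spec, seed = seed)
  std <- standardize_continuous_parents(data, miss_continuous_columns(spec$dgp_id))
  out <- data
  with_seed(seed, {
    M <- list()
    for (nd in spec$nodes) {
      lp <- intercepts[[nd$mnode]] + miss_node_lp(nd, std, spec$dgp_id, M)
      M[[nd$mnode]] <- rbinom(nrow(data), 1, plogis(lp))
    }
    for (nd in spec$nodes) {
      out[[nd$mnode]] <- M[[nd$mnode]]
      out[[nd$var]][M[[nd$mnode]] == 1] <- NA
    }
  })
  attr(out, "dgp_id") <- attr(data, "dgp_id")
  attr(out, "mdag") <- spec$name
  out
}

#' Generate one observed (post-missingness) dataset for a scenario
#'
#' Convenience wrapper: complete data via [generate_complete_data()], then
#' m-DAG missingness with the scenario's frozen calibrated intercepts.
#'
#' @inheritParams generate_complete_data
#' @return ObservedData data.frame (see [apply_missingness()]).
#' @export
generate_observed_data <- function(config, rep_index = 1L) {
  if (is.null(config$calibration)) config <- calibrate_scenario(config)
  dat <- generate_complete_data(config, rep_index)
  spec <- build_mdag(config$mdag, config$dgp_id, config$coeff$miss)
  apply_missingness(dat, spec,
                    seed = derive_seed(config$master_seed, rep_index, "missingness"),
                    intercepts = config$calibration$miss_intercepts)
}
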