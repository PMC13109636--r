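#' Write and read observed/complete datasets as CSV
#'
#' Plain UTF-8 comma-separated files with a header row; missing cells are
#' written as empty fields; indicator columns travel alongside the values, so
#' a written file round-trips through [read_observed_csv()].
#'
#' @param data data.frame (complete or observed).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_observed_csv <- function(data, path) {
  write.csv(data, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_observed_csv
#' @export
read_observed_csv <- function(path) {
  read.csv(path, na.strings = "")
}

#' Serialize and restore a scenario configuration
#'
#' The config (including any frozen calibration) is written as a structured
#' YAML text file; matrices are stored with their dimensions.
#'
#' @param config a [scenario_config()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_scenario_config <- function(config, path) {
  ser <- unclass(config)
  ser$coeff$copula <- list(values = as.numeric(config$coeff$copula),
                           dim = dim(config$coeff$copula),
                           names = rownames(config$coeff$copula))
  # yaml serializes named atomic vectors as plain sequences; maps keep names
  namify <- function(x) {
    if (is.list(x)) lapply(x, namify)
    else if (is.atomic(x) && !is.null(names(x))) as.list(x)
    else x
  }
  yaml::write_yaml(namify(ser), path)
  invisible(path)
}

#' @rdname write_scenario_config
#' @export
read_scenario_config <- function(path) {
  ser <- yaml::read_yaml(path)
  cop <- matrix(ser$coeff$copula$values, ser$coeff$copula$dim[1],
                ser$coeff$copula$dim[2],
                dimnames = list(ser$coeff$copula$names, ser$coeff$copula$names))
  ser$coeff$copula <- cop
  for (nm in setdiff(names(ser$coeff), c("copula", "miss")))
    ser$coeff[[nm]] <- unlist(ser$coeff[[nm]])
  ser$coeff$miss <- lapply(ser$coeff$miss, unlist)
  if (!is.null(ser$calibration))
    ser$calibration$miss_intercepts <- unlist(ser$calibration$miss_intercepts)
  structure(ser, class = "scenario_config")
}

#' Write a simulation summary as CSV
#'
#' @param summary a [run_study()] result.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_summary_csv <- function(summary, path) {
  write.csv(as.data.frame(summary), path, row.names = FALSE)
  invisible(path)
}

#' Generate small canned datasets for every DGP and m-DAG
#'
#' Writes one observed-data CSV per (DGP, m-DAG) combination at positivity
#' level 1 plus its scenario config, for use as test fixtures or worked
#' examples.
#'
#' @param out_dir output directory (created if needed).
#' @param n rows per dataset.
#' @param master_seed integer seed.
#' @param n_cal calibration-sample size (small by default: fixtures only).
#' @return character vector of written file paths, invisibly.
#' @export
make_fixtures <- function(out_dir, n = 200, master_seed = 1L, n_cal = 20000) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (dgp in 1:5) for (mdag in c("A", "B", "C", "D", "E")) {
    cfg <- scenario_config(dgp, 1, mdag, n = n, n_reps = 1,
                           master_seed = master_seed, n_cal = n_cal)
    cfg <- calibrate_scenario(cfg)
    obsd <- generate_observed_data(cfg, 1)
    p <- file.path(out_dir, sprintf("dgp%d_mdag%s.csv", dgp, mdag))
    write_observed_csv(obsd, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
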