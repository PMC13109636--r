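#' Derive a reproducible seed for one replicate and pipeline stage
#'
#' The laboratory draws every random quantity from a stream derived from a
#' single `master_seed` together with the replicate index and a stage name
#' ("complete", "missingness", "impute", ...).  Identical `(master_seed,
#' rep_index, stage)` triples always yield the same stream, so a scenario
#' regenerates bit-identically regardless of execution order or how many
#' replicates run in between.
#'
#' @param master_seed integer master seed of the scenario.
#' @param rep_index integer replicate index (0 is reserved for calibration).
#' @param stage character stage label.
#' @return a single integer in `[1, 2^31 - 2]` suitable for [set.seed()].
#' @export
derive_seed <- function(master_seed, rep_index = 0L, stage = "complete") {
  m <- 2147483647 # 2^31 - 1, Mersenne prime; keeps seeds in integer range
  h <- 0
  for (b in utf8ToInt(stage)) h <- (h * 131 + b) %% m
  s <- (abs(as.numeric(master_seed)) %% m) * 48271 %% m
  s <- (s + as.numeric(rep_index) * 69621 + h) %% m
  as.integer(s %% (m - 1) + 1)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(seed)
  expr
}
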