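# Block-based parameter estimation: parameters are grouped by biological
# subsystem and each block is fitted in turn against replicate-mean
# observables, which keeps the interdependence between parameters manageable
# in a stochastic model.

.CALIBRATION_BLOCKS <- list(
  collagen_producing_cells = c("k_prolif_ahsc", "k_prolif_tgfb",
                               "t_half_mfb_exit", "k_bind_base",
                               "mfb_bind_ratio"),
  reactMFB_inactivation = c("frac_reactmfb_inact"),
  iHSC_qHSC = c("t_half_ihsc_death", "t_half_qhsc_death",
                "t_half_qhsc_renewal"),
  collagen_turnover = c("col1_prod_base_ahsc", "k_deg_col1_high",
                        "k_deg_col1_low", "k_stabilize", "k_destabilize")
)

#' Parameter blocks used by the calibration procedure
#' @return Named list mapping block names to parameter names.
#' @export
calibration_blocks <- function() .CALIBRATION_BLOCKS

#' Define a calibration target
#'
#' @param observable One of the series columns (e.g. `"col1_total"`,
#'   `"alpha_sma"`) or a derived quantity: `"alpha_sma_fold"` (relative to
#'   the initial quiescent count), `"col1_fold"` (relative to the collagen
#'   baseline), `"ihsc_qhsc_ratio"`, `"total_cells"`.
#' @param time Hours at which the observable is read.
#' @param value Target value.
#' @param tolerance Acceptable relative deviation (used for reporting which
#'   targets are met; the objective itself is the sum of squared relative
#'   errors).
#' @return A one-row data.frame.
#' @export
calibration_target <- function(observable, time, value, tolerance = 0.1) {
  data.frame(observable = observable, time = time, value = value,
             tolerance = tolerance, stringsAsFactors = FALSE)
}

# replicate-mean value of a (possibly derived) observable at a time
.target_value <- function(agg, observable, time, params) {
  i <- which.min(abs(agg$time - time))
  col <- function(n) agg[[paste0(n, "_mean")]][i]
  switch(observable,
    alpha_sma_fold = col("alpha_sma") / params$n_init_qhsc,
    col1_fold = col("col1_total") / params$col1_baseline,
    ihsc_qhsc_ratio = col("iHSC") / (col("iHSC") + col("qHSC")),
    total_cells = col("qHSC") + col("iHSC") + col("alpha_sma") +
      col("apop_sene_MFB"),
    col(observable))
}

#' Calibrate one parameter block by grid search
#'
#' Evaluates every point of the grid (a named list of candidate values for a
#' subset of the block's parameters, expanded factorially), simulating
#' `n_replicates` runs under `protocol` with seeds derived from `seed`, and
#' keeps the point minimizing the sum of squared relative errors of the
#' replicate-mean observables against the targets. Deterministic given
#' `seed`: every grid point reuses the same replicate seeds.
#'
#' @param family Model family name.
#' @param params Starting `hsc_parameters`.
#' @param block One of `names(calibration_blocks())`.
#' @param targets Data.frame of [calibration_target()] rows.
#' @param search_grid Named list of candidate vectors; names must belong to
#'   the block. An empty or zero-width grid returns `params` unchanged.
#' @param seed Base seed.
#' @param n_replicates Replicates per grid point.
#' @param protocol Stimulation protocol (default: the chronic twice-weekly
#'   benchmark).
#' @param horizon Simulation horizon (hours); defaults to just past the last
#'   target time.
#' @return Updated `hsc_parameters` with a `"calibration"` attribute holding
#'   the grid table (including the achieved objective per point) and the
#'   per-target errors of the selected point.
#' @export
block_calibrate <- function(family, params, block, targets, search_grid,
                            seed = 1, n_replicates = 3,
                            protocol = kisseleva_protocol(10000),
                            horizon = NULL) {
  if (!block %in% names(.CALIBRATION_BLOCKS))
    stop("unknown calibration block: ", block)
  if (!is.list(search_grid))
    stop("search_grid must be a named list of candidate values")
  bad <- setdiff(names(search_grid), .CALIBRATION_BLOCKS[[block]])
  if (length(bad))
    stop("grid parameter(s) not in block '", block, "': ",
         paste(bad, collapse = ", "))
  if (length(search_grid) == 0 || any(lengths(search_grid) == 0))
    stop("empty search grid")
  stopifnot(nrow(targets) >= 1)
  horizon <- horizon %||% (max(targets$time) + 24)

  grid <- expand.grid(search_grid, KEEP.OUT.ATTRS = FALSE)
  objective <- numeric(nrow(grid))
  errors <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    p <- params
    for (n in names(grid)) p[[n]] <- grid[[n]][g]
    validate_parameters(p)
    rules <- build_rules(family, p)
    reps <- run_replicates(rules, initial_state(p), protocol,
                           horizon = horizon,
                           record_grid = sort(unique(c(0, targets$time))),
                           n_replicates = n_replicates, base_seed = seed)
    agg <- aggregate_replicates(reps)
    err <- vapply(seq_len(nrow(targets)), function(i) {
      v <- .target_value(agg, targets$observable[i], targets$time[i], p)
      (v - targets$value[i]) / targets$value[i]
    }, numeric(1))
    errors[[g]] <- err
    objective[g] <- sum(err^2)
  }
  best <- which.min(objective)
  out <- params
  for (n in names(grid)) out[[n]] <- grid[[n]][best]
  prov <- attr(out, "provenance")
  prov$provenance[prov$parameter %in% names(grid)] <- "estimated"
  attr(out, "provenance") <- prov
  grid$objective <- objective
  attr(out, "calibration") <- list(
    block = block, grid = grid, best = best,
    errors = setNames(errors[[best]], targets$observable),
    within_tolerance = abs(errors[[best]]) <= targets$tolerance)
  validate_parameters(out)
  out
}
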