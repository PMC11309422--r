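# Derived observables and replicate aggregation.
#
# The readouts mirror the published figures: alpha-SMA+ cells (the sum of
# activated, myofibroblast, reactivated and reactivated-myofibroblast
# counts), total collagen (sum of the two remodeling pools, arbitrary
# units), fold-changes against the pre-stimulation baseline, and the
# iHSC/qHSC balance during recovery.

#' Alpha-SMA positive cell count
#'
#' @param sample A row (or several rows) of an `hsc_timeseries`, or any
#'   data.frame with the state-count columns.
#' @return Numeric vector of aHSC + MFB + react_HSC + react_MFB.
#' @export
alpha_sma_count <- function(sample) {
  sample$aHSC + sample$MFB + sample$react_HSC + sample$react_MFB
}

#' Total collagen-I amount (a.u.)
#'
#' @inheritParams alpha_sma_count
#' @return `COL1_remodeling_high + COL1_remodeling_low`.
#' @export
col1_total <- function(sample) {
  sample$COL1_remodeling_high + sample$COL1_remodeling_low
}

#' Inactivated fraction of the quiescent-like pool
#'
#' @inheritParams alpha_sma_count
#' @return `iHSC / (iHSC + qHSC)`; `NA` when both counts are zero.
#' @export
ihsc_qhsc_ratio <- function(sample) {
  denom <- sample$iHSC + sample$qHSC
  ifelse(denom > 0, sample$iHSC / denom, NA_real_)
}

# value of an observable (a column name or a function of the series) at the
# grid time nearest to t
.observable_at <- function(series, observable, t) {
  i <- which.min(abs(series$time - t))
  v <- if (is.function(observable)) observable(series[i, , drop = FALSE])
  else series[[observable]][i]
  as.numeric(v)
}

#' Fold-change of an observable
#'
#' Ratio of an observable at time `t` to its value at the reference time
#' `t_ref` (both snapped to the nearest grid point). The reference defaults
#' to the pre-stimulation baseline at day 4. For the alpha-SMA count, whose
#' pre-stimulation value is zero, the published convention divides by the
#' baseline quiescent-cell count instead; pass `ref_value` to impose such an
#' external reference.
#'
#' @param series An `hsc_timeseries`.
#' @param observable Column name (e.g. `"col1_total"`, `"alpha_sma"`) or a
#'   function of a sample row.
#' @param t Time (hours) of the numerator.
#' @param t_ref Reference time (hours); default 96 (day 4).
#' @param ref_value Optional externally imposed reference value.
#' @return The fold-change, or `NA` if the reference is zero.
#' @export
fold_change <- function(series, observable, t, t_ref = 96,
                        ref_value = NULL) {
  num <- .observable_at(series, observable, t)
  ref <- ref_value %||% .observable_at(series, observable, t_ref)
  if (!is.finite(ref) || ref <= 0) return(NA_real_)
  num / ref
}

#' Aggregate replicate time series
#'
#' Per-time mean and sample standard deviation of every numeric column
#' across replicates. All replicates must share the record grid exactly;
#' mismatched grids are an error, never interpolated.
#'
#' @param series_list List of `hsc_timeseries` with identical grids.
#' @return A data.frame with columns `time`, then `<column>_mean` and
#'   `<column>_sd` for each observable, plus `n` (replicate count).
#' @export
aggregate_replicates <- function(series_list) {
  stopifnot(length(series_list) >= 1)
  times <- series_list[[1]]$time
  for (s in series_list[-1]) {
    if (length(s$time) != length(times) || any(s$time != times))
      stop("replicate record grids differ; refusing to aggregate")
  }
  cols <- setdiff(names(series_list[[1]]), "time")
  out <- data.frame(time = times)
  for (cn in cols) {
    m <- vapply(series_list, function(s) s[[cn]], numeric(length(times)))
    m <- matrix(m, nrow = length(times))
    out[[paste0(cn, "_mean")]] <- rowMeans(m)
    out[[paste0(cn, "_sd")]] <- apply(m, 1, sd)
  }
  out$n <- length(series_list)
  out
}

#' Write a time series (or replicate summary) to CSV
#'
#' Raw series are written with the documented column order: time, the seven
#' cell-state counts, the four token amounts, then `alpha_sma` and
#' `col1_total`.
#'
#' @param ts An `hsc_timeseries` or summary data.frame.
#' @param path Output file.
#' @export
write_timeseries_csv <- function(ts, path) {
  lead <- c("time", hsc_cell_states(), hsc_token_names(),
            "alpha_sma", "col1_total")
  ord <- c(intersect(lead, names(ts)), setdiff(names(ts), lead))
  write.csv(as.data.frame(ts)[, ord], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_timeseries_csv
#' @export
read_timeseries_csv <- function(path) {
  ts <- read.csv(path, check.names = FALSE)
  class(ts) <- c("hsc_timeseries", class(ts))
  ts
}
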