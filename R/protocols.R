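# Stimulation protocols: timed additions of free TGFbeta1, encoded as
# perturbation lists. Doses are molecules per living cell, resolved at the
# moment each stimulation fires. All times are hours; convenience constants
# below keep the schedules readable.

.DAY <- 24
.WEEK <- 7 * 24
.MONTH <- 30 * 24  # calendar month approximated as 30 days

#' Construct a stimulation protocol
#'
#' @param name Protocol label carried into outputs.
#' @param times Strictly increasing stimulation times (hours).
#' @param dose Molecules of TGFbeta1 per living cell added at each time
#'   (a scalar, or one value per time).
#' @param horizon Simulation horizon (hours).
#' @param per_cell Resolve doses against the living-cell count at event time
#'   (default); `FALSE` treats doses as absolute token amounts.
#' @return An object of class `hsc_protocol` with an `events` list of
#'   [perturbation()]s.
#' @export
stimulation_protocol <- function(name, times, dose, horizon,
                                 per_cell = TRUE) {
  stopifnot(is.numeric(times), all(dose >= 0), horizon > 0)
  if (length(times) && any(diff(times) <= 0))
    stop("stimulation times must be strictly increasing")
  dose <- rep_len(dose, length(times))
  events <- mapply(function(t, d)
    perturbation(t, c(TGFB1_free = d), per_cell = per_cell),
    times, dose, SIMPLIFY = FALSE)
  pr <- list(name = name, events = events, times = times, dose = dose,
             dose_per_cell = if (length(dose)) dose[[1]] else 0,
             horizon = horizon)
  class(pr) <- "hsc_protocol"
  pr
}

#' @export
print.hsc_protocol <- function(x, ...) {
  cat("<hsc_protocol>", x$name, "-", length(x$events), "stimulations,",
      "horizon", x$horizon / .DAY, "days\n")
  if (length(x$times))
    cat("  times (d):", paste(signif(x$times / .DAY, 4), collapse = ", "),
        "\n  dose:", paste(unique(x$dose), collapse = ", "),
        "molecules/cell\n")
  invisible(x)
}

#' Chronic twice-weekly stimulation with reversion
#'
#' The benchmark fibrosis/reversion schedule: 16 stimulations at 3.5-day
#' intervals (twice a week for two months), the first on day 4 so the model
#' can equilibrate, followed by six months without stimulation.
#'
#' @param dose Molecules of TGFbeta1 per cell and stimulation (default
#'   10,000, the receptor-saturating dose).
#' @param n_stimulations Number of stimulations (default 16).
#' @param reversion_months Months of follow-up after the last stimulation.
#' @return An `hsc_protocol`.
#' @export
kisseleva_protocol <- function(dose = 10000, n_stimulations = 16,
                               reversion_months = 6) {
  stopifnot(dose >= 0)
  times <- 4 * .DAY + 3.5 * .DAY * (seq_len(n_stimulations) - 1)
  horizon <- max(times) + reversion_months * .MONTH
  stimulation_protocol("kisseleva-2x-week", times, dose, horizon)
}

#' CCl4-like mouse schedule
#'
#' Three stimulations in the first week, then one per week: for ten weeks in
#' the fibrosis arm, or for four weeks in the reversion arm (which is then
#' followed for at least eight stimulation-free weeks).
#'
#' @param dose Molecules per cell (default 10,000; the injury is modeled as
#'   receptor-saturating).
#' @param reversion Use the truncated reversion arm.
#' @return An `hsc_protocol`.
#' @export
ccl4_mouse_protocol <- function(dose = 10000, reversion = FALSE) {
  first_week <- c(0, 2, 4) * .DAY
  n_weekly <- if (reversion) 4 else 10
  weekly <- .WEEK * seq_len(n_weekly)
  times <- c(first_week, weekly)
  horizon <- if (reversion) max(times) + 8 * .WEEK else max(times) + 2 * .WEEK
  stimulation_protocol(
    if (reversion) "ccl4-mouse-reversion" else "ccl4-mouse-fibrosis",
    times, dose, horizon)
}

#' Relapse (injury/recovery) cycles
#'
#' Each cycle is one month of injury (8 stimulations at 3.5-day intervals)
#' followed by six months of recovery; cycles are concatenated.
#'
#' @param n_cycles Number of injury/recovery cycles (>= 1).
#' @param dose Molecules per cell.
#' @return An `hsc_protocol`.
#' @export
relapse_protocol <- function(n_cycles = 2, dose = 10000) {
  stopifnot(n_cycles >= 1)
  cycle_len <- .MONTH + 6 * .MONTH
  times <- unlist(lapply(seq_len(n_cycles) - 1, function(cy)
    cy * cycle_len + 3.5 * .DAY * (0:7)))
  horizon <- n_cycles * cycle_len
  stimulation_protocol(sprintf("relapse-%d-cycles", n_cycles), times, dose,
                       horizon)
}

#' Dose / stimulus-count / periodicity protocol grid
#'
#' Cartesian product of TGFbeta1 doses, stimulation counts and periodicities,
#' one protocol per combination, first stimulation on day 4. The defaults
#' reproduce the published sensitivity scan: doses 10 to 100,000 molecules
#' per cell, 2 to 32 stimulations, periodicities from 22.5 hours to 60 days.
#'
#' @param doses Molecules per cell.
#' @param n_stimuli_list Stimulation counts.
#' @param periodicities Hours between stimulations.
#' @param follow_up Hours simulated beyond the last stimulation.
#' @return A list of `hsc_protocol` objects.
#' @export
dose_periodicity_grid <- function(doses = c(10, 100, 1000, 1e4, 1e5),
                                  n_stimuli_list = c(2, 4, 8, 16, 32),
                                  periodicities = c(22.5, 45, 90, 180,
                                                    15 * 24, 30 * 24,
                                                    60 * 24),
                                  follow_up = 60 * .DAY) {
  stopifnot(length(doses) > 0, length(n_stimuli_list) > 0,
            length(periodicities) > 0)
  grid <- expand.grid(dose = doses, n = n_stimuli_list, per = periodicities)
  lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    times <- 4 * .DAY + g$per * (seq_len(g$n) - 1)
    stimulation_protocol(
      sprintf("scan_dose%g_n%d_per%gh", g$dose, g$n, g$per),
      times, g$dose, max(times) + follow_up)
  })
}
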