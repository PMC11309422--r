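# Parameter table for the HSC model families.
#
# Every quantity documented as a duration is stored in hours. Durations of
# exponential elimination/exit processes are half-lives and are converted to
# rates as log(2)/t_half (a 1/t alternative is available as a switch);
# durations of paced processes (counter stepping, receptor trafficking,
# state-boundary transitions) are mean sojourn times, converted as 1/t.

#' Convert a half-life to a first-order rate
#'
#' @param t_half Half-life in hours.
#' @param mode `"exponential"` (rate = log(2)/t_half, the default) or
#'   `"reciprocal"` (rate = 1/t_half).
#' @return Rate per hour.
#' @export
rate_from_halflife <- function(t_half, mode = c("exponential", "reciprocal")) {
  mode <- match.arg(mode)
  if (mode == "exponential") log(2) / t_half else 1 / t_half
}

# provenance tags: "literature", "calculated", "estimated" (block calibration
# against the published fold-change constraints), "default" (package choice)
.PARAM_TABLE <- list(
  # -- initial population ---------------------------------------------------
  n_init_qhsc = list(100, "default",
                     "initial quiescent cells; fold observables are scale-free"),
  # -- quiescent cell turnover ----------------------------------------------
  t_half_qhsc_death = list(1400, "estimated",
                           "qHSC half-life (h); sets the renewal time scale"),
  t_half_qhsc_renewal = list(1400, "estimated",
                             "qHSC renewal half-time (h); creation rate is n_init * log(2)/t"),
  # -- TGFbeta1 binding -----------------------------------------------------
  k_bind_base = list(2.6e-7, "estimated",
                     "binding rate per free-TGFB1 unit per hour (qHSC/aHSC/iHSC/react_HSC)"),
  mfb_bind_ratio = list(0.1, "literature",
                        "receptor-poor MFB/react_MFB binding rate relative to qHSC"),
  t_half_tgfb1 = list(12, "estimated",
                      "first-order clearance half-life of free TGFB1 (h)"),
  tgfb1_clearance_quantum = list(100, "default",
                                 "token units removed per bulk clearance event (propensity rescaled so first-order kinetics are unchanged)"),
  # -- receptor trafficking -------------------------------------------------
  t_trafficking_tgfbr = list(0.5, "literature",
                             "mean membrane<->cytosol trafficking time of the receptor complex (h)"),
  frac_recycle = list(0.9, "literature",
                      "fraction of internalized receptors recycled rather than degraded"),
  k_tgfbr_synthesis = list(0.1, "estimated",
                           "replacement rate of degraded receptors (per h)"),
  # -- activation / differentiation ----------------------------------------
  t_half_signal_init = list(4, "estimated",
                            "half-time for a bound receptor to commit the activation signal (h)"),
  ihsc_speedup = list(3.5, "literature",
                      "fold acceleration of signal initiation in inactivated cells"),
  n_steps = list(14, "literature",
                 "counter steps from quiescence to full myofibroblast (14 d in vitro)"),
  t_per_step = list(24, "literature",
                    "mean duration of one differentiation step (h)"),
  t_state_transition = list(1, "default",
                            "mean dwell at the aHSC/MFB (and react) boundary before the state flips (h)"),
  # -- proliferation --------------------------------------------------------
  k_prolif_ahsc = list(2e-4, "estimated",
                       "basal aHSC division rate (per h); MFB rate is mfb_prolif_ratio times this"),
  mfb_prolif_ratio = list(0.5, "literature",
                          "MFB/aHSC basal proliferation ratio (aHSC divide twice as fast)"),
  k_prolif_tgfb = list(0.0095, "estimated",
                       "division rate of a TGFB1-bound aHSC/react_HSC (per h); consumes the signal"),
  ahsc_prolif_min_step = list(3, "literature",
                              "first counter step at which aHSC divide"),
  reacthsc_prolif_min_step = list(0, "literature",
                                  "react_HSC divide from the first reactivation step"),
  # -- collagen -------------------------------------------------------------
  col1_prod_base_ahsc = list(2.65e-4, "estimated",
                             "basal COL1 output of an aHSC, a.u. per hour per counter unit"),
  mfb_basal_ratio = list(10, "literature",
                         "MFB basal COL1 output relative to aHSC"),
  tgfb_boost_ahsc = list(10, "literature",
                         "fold increase of COL1 output while an aHSC/react_HSC is bound"),
  tgfb_boost_mfb = list(2, "literature",
                        "fold increase of COL1 output while an MFB/react_MFB is bound"),
  k_deg_col1_high = list(0.005, "estimated",
                         "degradation rate of high-remodeling COL1 (per h)"),
  k_deg_col1_low = list(2.4e-4, "estimated",
                        "degradation rate of low-remodeling COL1 (per h); slower than high"),
  k_stabilize = list(2.2e-6, "estimated",
                     "high->low conversion rate per alpha-SMA+ cell (per h)"),
  k_destabilize = list(1.5e-4, "estimated",
                       "low->high conversion rate (per h)"),
  col1_baseline = list(100, "default",
                       "healthy-liver COL1 level, a.u.; 100 keeps 14-fold resolution above the token quantum"),
  # -- myofibroblast exit ---------------------------------------------------
  t_half_mfb_exit = list(170, "estimated",
                         "half-life of an unbound MFB/react_MFB before exit (h)"),
  frac_mfb_inact = list(0.45, "literature",
                        "fraction of exiting MFBs that inactivate (remainder apoptose/senesce)"),
  frac_reactmfb_inact = list(0.05, "estimated",
                             "fraction of exiting react_MFBs that inactivate (families 2-3)"),
  t_half_apop_sene_clear = list(168, "estimated",
                                "clearance half-life of apoptotic/senescent MFBs (h)"),
  t_half_ihsc_death = list(4500, "estimated",
                           "slow elimination half-life of inactivated cells (h)"),
  frac_ihsc_revert = list(0.5, "default",
                          "fraction of exiting iHSCs that revert to quiescence (family 3 only)"),
  # -- conventions ----------------------------------------------------------
  halflife_mode = list("exponential", "default",
                       "half-life to rate conversion: log(2)/t (exponential) or 1/t"),
  dose_basis = list("per_living_cell", "default",
                    "per-cell doses resolved against living cells at the event (or 'initial')")
)

#' Default parameter table for a model family
#'
#' Returns the fully populated parameter set used by [build_rules()]. Values
#' tagged `literature` or `calculated` restate published measurements
#' (activation takes 14 daily steps with the quiescent-to-activated switch at
#' step 7; 45% of exiting myofibroblasts inactivate; inactivated cells
#' respond 3.5-fold faster; myofibroblasts produce 10-fold more basal
#' collagen but receive only a 2-fold bound-signal boost against 10-fold for
#' activated cells). Values tagged `estimated` were fixed by block
#' calibration against the chronic twice-weekly stimulation benchmark
#' (12-fold collagen at one month, 14-fold at two months, 1.43-fold
#' alpha-SMA+ cells at two months, 50/50 iHSC/qHSC after one month of
#' recovery, return to the initial cell count after six months); see
#' [block_calibrate()]. Provenance and a one-line description of every entry
#' are attached as the `"provenance"` attribute.
#'
#' @param family One of `"reactMFB-wo-inactivation"`,
#'   `"reactMFB-with-inactivation"`, `"iHSC-reversion-to-qHSC"`.
#' @return A named list of class `hsc_parameters`.
#' @export
default_parameters <- function(family = c("reactMFB-with-inactivation",
                                          "reactMFB-wo-inactivation",
                                          "iHSC-reversion-to-qHSC")) {
  family <- match.arg(family)
  params <- lapply(.PARAM_TABLE, `[[`, 1)
  prov <- data.frame(
    parameter = names(.PARAM_TABLE),
    provenance = vapply(.PARAM_TABLE, `[[`, "", 2),
    description = vapply(.PARAM_TABLE, `[[`, "", 3),
    stringsAsFactors = FALSE
  )
  params$family <- family
  attr(params, "provenance") <- prov
  class(params) <- "hsc_parameters"
  validate_parameters(params)
  params
}

#' Validate a parameter table
#'
#' @param params An `hsc_parameters` list.
#' @return Invisibly `params`; stops on violation.
#' @export
validate_parameters <- function(params) {
  p <- params
  fr <- c("frac_recycle", "frac_mfb_inact", "frac_reactmfb_inact",
          "frac_ihsc_revert", "mfb_bind_ratio", "mfb_prolif_ratio")
  for (f in fr) {
    v <- p[[f]]
    if (!is.numeric(v) || v < 0 || v > 1)
      stop("parameter ", f, " must lie in [0, 1]")
  }
  pos <- c("t_half_qhsc_death", "t_half_qhsc_renewal", "k_bind_base",
           "t_half_tgfb1", "t_trafficking_tgfbr", "k_tgfbr_synthesis",
           "t_half_signal_init", "ihsc_speedup", "t_per_step",
           "t_state_transition", "k_prolif_ahsc", "k_prolif_tgfb",
           "col1_prod_base_ahsc", "mfb_basal_ratio", "tgfb_boost_ahsc",
           "tgfb_boost_mfb", "k_deg_col1_high", "k_deg_col1_low",
           "k_stabilize", "k_destabilize", "col1_baseline", "t_half_mfb_exit",
           "t_half_apop_sene_clear", "t_half_ihsc_death", "n_init_qhsc")
  for (f in pos) {
    v <- p[[f]]
    if (!is.numeric(v) || !is.finite(v) || v <= 0)
      stop("parameter ", f, " must be a positive number")
  }
  if (p$k_deg_col1_low >= p$k_deg_col1_high)
    stop("k_deg_col1_low must be smaller than k_deg_col1_high")
  if (p$n_steps != 14)
    stop("the counter schema is fixed at 14 steps")
  if (!p$halflife_mode %in% c("exponential", "reciprocal"))
    stop("halflife_mode must be 'exponential' or 'reciprocal'")
  if (!p$dose_basis %in% c("per_living_cell", "initial"))
    stop("dose_basis must be 'per_living_cell' or 'initial'")
  invisible(params)
}

#' @export
print.hsc_parameters <- function(x, ...) {
  cat("<hsc_parameters> family:", x$family, "\n")
  prov <- attr(x, "provenance")
  vals <- vapply(prov$parameter, function(n) {
    v <- x[[n]]
    if (is.numeric(v)) format(v, digits = 4) else as.character(v)
  }, "")
  print(data.frame(value = vals, provenance = prov$provenance,
                   row.names = prov$parameter))
  invisible(x)
}

#' Read or write a parameter table
#'
#' Parameters are exchanged as a flat YAML mapping (one `name: value` pair
#' per parameter) or, with the readxl package installed, as a two-column
#' `parameter` / `value` spreadsheet in the style of a supplementary
#' parameter table. Unknown names are rejected; missing names keep their
#' defaults.
#'
#' @param path File path (`.yaml`/`.yml` or `.xlsx`).
#' @param family Model family for the defaults that absent keys fall back to.
#' @return An `hsc_parameters` list.
#' @export
read_parameters <- function(path, family = "reactMFB-with-inactivation") {
  if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading spreadsheet parameter tables requires the readxl package")
    sheet <- as.data.frame(readxl::read_excel(path))
    if (!all(c("parameter", "value") %in% names(sheet)))
      stop("parameter spreadsheet needs 'parameter' and 'value' columns")
    vals <- as.list(sheet$value)
    names(vals) <- sheet$parameter
    num <- suppressWarnings(lapply(vals, function(v)
      if (is.character(v) && !is.na(as.numeric(v))) as.numeric(v) else v))
    vals <- num
  } else {
    vals <- yaml::read_yaml(path)
  }
  if (!is.null(vals$family)) {
    family <- vals$family
    vals$family <- NULL
  }
  params <- default_parameters(family)
  bad <- setdiff(names(vals), names(.PARAM_TABLE))
  if (length(bad)) stop("unknown parameter(s) in ", path, ": ",
                        paste(bad, collapse = ", "))
  prov <- attr(params, "provenance")
  for (n in names(vals)) {
    params[[n]] <- vals[[n]]
    prov$provenance[prov$parameter == n] <- "file"
  }
  attr(params, "provenance") <- prov
  validate_parameters(params)
  params
}

#' @rdname read_parameters
#' @param params An `hsc_parameters` list to serialize.
#' @export
write_parameters <- function(params, path) {
  vals <- unclass(params)
  attr(vals, "provenance") <- NULL
  yaml::write_yaml(vals, path)
  invisible(path)
}
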