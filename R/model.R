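# Rule-set builder for the three HSC model families.
#
# The three families are nested: the base family has no react_MFB
# inactivation; the second adds a single inactivation rule for react_MFBs
# (splitting their exit between apoptosis/senescence and the inactivated
# state); the third additionally lets exiting iHSCs revert to quiescence.

#' Names of the model families
#' @return Character vector of the three family names.
#' @export
model_families <- function() {
  c("reactMFB-wo-inactivation", "reactMFB-with-inactivation",
    "iHSC-reversion-to-qHSC")
}

#' Build the complete rule set for a model family
#'
#' Emits the seven biological rule groups plus free-TGFbeta1 clearance:
#'
#' 1. `qhsc_renewal` - creation and degradation of free quiescent cells.
#' 2. `tgfb1_binding` - one binding rule per cell state (rate proportional
#'    to the free-TGFB1 pool; receptor-poor MFB/react_MFB bind more slowly;
#'    cells committed to apoptosis/senescence carry a dead rule at rate 0).
#'    Binding moves one token from the free to the bound pool, occupies the
#'    binding site and internalizes the receptor.
#' 3. `tgfbr_turnover` - recycling and degradation of internalized
#'    receptors (mean trafficking time 30 min) and slow resynthesis.
#' 4. `activation` - bound-signal state switches qHSC->aHSC and
#'    iHSC->react_HSC (3.5-fold faster), daily counter stepping with the
#'    paired control counter as upper bound, and the aHSC->MFB /
#'    react_HSC->react_MFB switches at the step-7 boundary.
#' 5. `proliferation` - 30 rules enumerated per counter value: basal
#'    division of free aHSCs (steps 3-7), MFBs and react_MFBs (steps 8-14,
#'    at half the aHSC rate), plus 11 signal-consuming divisions of bound
#'    aHSCs (steps 3-7) and react_HSCs (steps 0-5). Daughters copy every
#'    site except the receptor (membrane) and the binding site (free).
#' 6. `col1` - 12 rules: 8 production rules (basal for free cells, boosted
#'    signal-consuming for bound cells; output proportional to the counter;
#'    myofibroblast basal output 10x the activated-cell output; bound boost
#'    10x for aHSC/react_HSC, 2x for MFB/react_MFB), degradation of each
#'    collagen pool (low-remodeling slower), stabilization high->low
#'    proportional to the alpha-SMA+ cell count, and constant-rate
#'    destabilization low->high.
#' 7. `mfb_exit` - exit of unbound myofibroblasts, split between
#'    apoptosis/senescence and inactivation (counter reset to 0) with the
#'    45/55 split for MFBs; clearance of apoptotic/senescent cells
#'    (enumerated per counter class) and slow iHSC elimination. Families 2-3
#'    add the react_MFB inactivation split; family 3 splits iHSC exit
#'    between elimination and reversion to quiescence.
#' 8. `tgfb1_clearance` - first-order decay of free TGFbeta1.
#'
#' The emitted rule counts are 75, 76 and 77 for the three families.
#'
#' @param family One of [model_families()].
#' @param params An `hsc_parameters` table from [default_parameters()].
#' @return A list of [hsc_rule()] objects with a `group` label each.
#' @export
build_rules <- function(family = NULL, params = NULL) {
  if (is.null(params)) params <- default_parameters(family %||% "reactMFB-with-inactivation")
  family <- family %||% params$family
  if (!family %in% model_families())
    stop("unknown model family: ", family)
  validate_parameters(params)
  p <- params
  h2r <- function(t) rate_from_halflife(t, p$halflife_mode)
  rules <- list()
  add <- function(r) rules[[length(rules) + 1L]] <<- r

  # -- 1. qHSC renewal ------------------------------------------------------
  add(hsc_rule("qhsc_death",
               guard = list(cell_state = "qHSC", tgfb1_binding = "free"),
               effect = list(delete = TRUE),
               rate_law = list(base_rate = h2r(p$t_half_qhsc_death)),
               group = "qhsc_renewal"))
  add(hsc_rule("qhsc_creation",
               guard = NULL,
               effect = list(create = agent_state("qHSC")),
               rate_law = list(base_rate = p$n_init_qhsc *
                                 h2r(p$t_half_qhsc_renewal)),
               group = "qhsc_renewal"))

  # -- 2. TGFB1 binding -----------------------------------------------------
  k_bind <- c(qHSC = p$k_bind_base, aHSC = p$k_bind_base,
              MFB = p$k_bind_base * p$mfb_bind_ratio,
              iHSC = p$k_bind_base, react_HSC = p$k_bind_base,
              react_MFB = p$k_bind_base * p$mfb_bind_ratio,
              apop_sene_MFB = 0)  # dead-end state does not signal
  for (s in hsc_cell_states()) {
    add(hsc_rule(paste0("bind_", s),
                 guard = list(cell_state = s, tgfb1_binding = "free",
                              tgfbr = "membrane"),
                 effect = list(tgfb1_binding = "bound", tgfbr = "internalized",
                               tokens = c(TGFB1_free = -1, TGFB1_bound = 1)),
                 rate_law = list(base_rate = k_bind[[s]],
                                 token_factor = "TGFB1_free"),
                 group = "tgfb1_binding"))
  }

  # -- 3. receptor turnover -------------------------------------------------
  k_traffic <- 1 / p$t_trafficking_tgfbr
  add(hsc_rule("tgfbr_recycling",
               guard = list(tgfbr = "internalized"),
               effect = list(tgfbr = "membrane"),
               rate_law = list(base_rate = p$frac_recycle * k_traffic),
               group = "tgfbr_turnover"))
  add(hsc_rule("tgfbr_degradation",
               guard = list(tgfbr = "internalized"),
               effect = list(tgfbr = "degraded"),
               rate_law = list(base_rate = (1 - p$frac_recycle) * k_traffic),
               group = "tgfbr_turnover"))
  add(hsc_rule("tgfbr_synthesis",
               guard = list(tgfbr = "degraded"),
               effect = list(tgfbr = "membrane"),
               rate_law = list(base_rate = p$k_tgfbr_synthesis),
               group = "tgfbr_turnover"))

  # -- 4. activation and differentiation ------------------------------------
  k_sig <- h2r(p$t_half_signal_init)
  k_step <- 1 / p$t_per_step
  k_trans <- 1 / p$t_state_transition
  add(hsc_rule("activation_qhsc",
               guard = list(cell_state = "qHSC", tgfb1_binding = "bound"),
               effect = list(cell_state = "aHSC", tgfb1_binding = "free",
                             tokens = c(TGFB1_bound = -1)),
               rate_law = list(base_rate = k_sig),
               group = "activation"))
  add(hsc_rule("reactivation_ihsc",
               guard = list(cell_state = "iHSC", tgfb1_binding = "bound"),
               effect = list(cell_state = "react_HSC", tgfb1_binding = "free",
                             tokens = c(TGFB1_bound = -1)),
               rate_law = list(base_rate = k_sig * p$ihsc_speedup),
               group = "activation"))
  add(hsc_rule("step_ahsc",
               guard = list(cell_state = "aHSC", step_max = 6),
               effect = list(step_delta = 1),
               rate_law = list(base_rate = k_step),
               group = "activation"))
  add(hsc_rule("step_react_hsc",
               guard = list(cell_state = "react_HSC", step_max = 6),
               effect = list(step_delta = 1),
               rate_law = list(base_rate = k_step),
               group = "activation"))
  add(hsc_rule("differentiation_ahsc_mfb",
               guard = list(cell_state = "aHSC", step_min = 7, step_max = 7),
               effect = list(cell_state = "MFB"),
               rate_law = list(base_rate = k_trans),
               group = "activation"))
  add(hsc_rule("differentiation_react_mfb",
               guard = list(cell_state = "react_HSC", step_min = 7,
                            step_max = 7),
               effect = list(cell_state = "react_MFB"),
               rate_law = list(base_rate = k_trans),
               group = "activation"))
  add(hsc_rule("step_mfb",
               guard = list(cell_state = "MFB", step_min = 7, step_max = 13),
               effect = list(step_delta = 1),
               rate_law = list(base_rate = k_step),
               group = "activation"))
  add(hsc_rule("step_react_mfb",
               guard = list(cell_state = "react_MFB", step_min = 7,
                            step_max = 13),
               effect = list(step_delta = 1),
               rate_law = list(base_rate = k_step),
               group = "activation"))

  # -- 5. proliferation (one rule per counter value, as in the source
  #       encoding where daughters need explicit counter values) ------------
  prolif <- function(state, step, rate, tgfb) {
    guard <- list(cell_state = state, step_min = step, step_max = step,
                  tgfb1_binding = if (tgfb) "bound" else "free")
    effect <- if (tgfb)
      list(daughter = TRUE, tgfb1_binding = "free",
           tokens = c(TGFB1_bound = -1))
    else list(daughter = TRUE)
    hsc_rule(sprintf("prolif_%s%s_s%d", state, if (tgfb) "_tgfb" else "", step),
             guard = guard, effect = effect,
             rate_law = list(base_rate = rate), group = "proliferation")
  }
  for (s in p$ahsc_prolif_min_step:7)
    add(prolif("aHSC", s, p$k_prolif_ahsc, FALSE))
  for (s in 8:14)
    add(prolif("MFB", s, p$k_prolif_ahsc * p$mfb_prolif_ratio, FALSE))
  for (s in 8:14)
    add(prolif("react_MFB", s, p$k_prolif_ahsc * p$mfb_prolif_ratio, FALSE))
  for (s in p$ahsc_prolif_min_step:7)
    add(prolif("aHSC", s, p$k_prolif_tgfb, TRUE))
  for (s in p$reacthsc_prolif_min_step:5)
    add(prolif("react_HSC", s, p$k_prolif_tgfb, TRUE))

  # -- 6. collagen turnover -------------------------------------------------
  col_base <- c(aHSC = p$col1_prod_base_ahsc,
                react_HSC = p$col1_prod_base_ahsc,
                MFB = p$col1_prod_base_ahsc * p$mfb_basal_ratio,
                react_MFB = p$col1_prod_base_ahsc * p$mfb_basal_ratio)
  col_boost <- c(aHSC = p$tgfb_boost_ahsc, react_HSC = p$tgfb_boost_ahsc,
                 MFB = p$tgfb_boost_mfb, react_MFB = p$tgfb_boost_mfb)
  for (s in names(col_base)) {
    add(hsc_rule(paste0("col1_prod_", s),
                 guard = list(cell_state = s, tgfb1_binding = "free"),
                 effect = list(tokens = c(COL1_remodeling_high = 1)),
                 rate_law = list(base_rate = col_base[[s]],
                                 counter_factor = TRUE),
                 group = "col1"))
  }
  for (s in names(col_base)) {
    add(hsc_rule(paste0("col1_prod_tgfb_", s),
                 guard = list(cell_state = s, tgfb1_binding = "bound"),
                 effect = list(tgfb1_binding = "free",
                               tokens = c(COL1_remodeling_high = 1,
                                          TGFB1_bound = -1)),
                 rate_law = list(base_rate = col_base[[s]] * col_boost[[s]],
                                 counter_factor = TRUE),
                 group = "col1"))
  }
  add(hsc_rule("col1_deg_high", guard = NULL,
               effect = list(tokens = c(COL1_remodeling_high = -1)),
               rate_law = list(base_rate = p$k_deg_col1_high,
                               token_factor = "COL1_remodeling_high"),
               group = "col1"))
  add(hsc_rule("col1_deg_low", guard = NULL,
               effect = list(tokens = c(COL1_remodeling_low = -1)),
               rate_law = list(base_rate = p$k_deg_col1_low,
                               token_factor = "COL1_remodeling_low"),
               group = "col1"))
  add(hsc_rule("col1_stabilization", guard = NULL,
               effect = list(tokens = c(COL1_remodeling_high = -1,
                                        COL1_remodeling_low = 1)),
               rate_law = list(base_rate = p$k_stabilize,
                               token_factor = "COL1_remodeling_high",
                               population_factor = "alpha_sma"),
               group = "col1"))
  add(hsc_rule("col1_destabilization", guard = NULL,
               effect = list(tokens = c(COL1_remodeling_low = -1,
                                        COL1_remodeling_high = 1)),
               rate_law = list(base_rate = p$k_destabilize,
                               token_factor = "COL1_remodeling_low"),
               group = "col1"))

  # -- 7. myofibroblast exit (only unbound cells exit) ----------------------
  k_exit <- h2r(p$t_half_mfb_exit)
  add(hsc_rule("mfb_apoptosis_senescence",
               guard = list(cell_state = "MFB", tgfb1_binding = "free"),
               effect = list(cell_state = "apop_sene_MFB"),
               rate_law = list(base_rate = k_exit * (1 - p$frac_mfb_inact)),
               group = "mfb_exit"))
  add(hsc_rule("mfb_inactivation",
               guard = list(cell_state = "MFB", tgfb1_binding = "free"),
               effect = list(cell_state = "iHSC", step_set = 0),
               rate_law = list(base_rate = k_exit * p$frac_mfb_inact),
               group = "mfb_exit"))
  react_inact <- if (family == "reactMFB-wo-inactivation") 0 else
    p$frac_reactmfb_inact
  add(hsc_rule("reactmfb_apoptosis_senescence",
               guard = list(cell_state = "react_MFB", tgfb1_binding = "free"),
               effect = list(cell_state = "apop_sene_MFB"),
               rate_law = list(base_rate = k_exit * (1 - react_inact)),
               group = "mfb_exit"))
  if (family != "reactMFB-wo-inactivation") {
    add(hsc_rule("reactmfb_inactivation",
                 guard = list(cell_state = "react_MFB",
                              tgfb1_binding = "free"),
                 effect = list(cell_state = "iHSC", step_set = 0),
                 rate_law = list(base_rate = k_exit * react_inact),
                 group = "mfb_exit"))
  }
  for (s in 7:14) {
    add(hsc_rule(sprintf("apop_sene_clearance_s%d", s),
                 guard = list(cell_state = "apop_sene_MFB", step_min = s,
                              step_max = s),
                 effect = list(delete = TRUE),
                 rate_law = list(base_rate = h2r(p$t_half_apop_sene_clear)),
                 group = "mfb_exit"))
  }
  ihsc_revert <- if (family == "iHSC-reversion-to-qHSC") p$frac_ihsc_revert
  else 0
  add(hsc_rule("ihsc_death",
               guard = list(cell_state = "iHSC", tgfb1_binding = "free"),
               effect = list(delete = TRUE),
               rate_law = list(base_rate = h2r(p$t_half_ihsc_death) *
                                 (1 - ihsc_revert)),
               group = "mfb_exit"))
  if (family == "iHSC-reversion-to-qHSC") {
    add(hsc_rule("ihsc_reversion",
                 guard = list(cell_state = "iHSC", tgfb1_binding = "free"),
                 effect = list(cell_state = "qHSC", step_set = 0),
                 rate_law = list(base_rate = h2r(p$t_half_ihsc_death) *
                                   ihsc_revert),
                 group = "mfb_exit"))
  }

  # -- 8. free TGFB1 clearance ---------------------------------------------
  # bulk pool: each event removes one quantum of delta units at propensity
  # (k/delta)|T|, preserving the first-order mean d|T|/dt = -k|T|
  dq <- p$tgfb1_clearance_quantum
  add(hsc_rule("tgfb1_clearance", guard = NULL,
               effect = list(tokens = c(TGFB1_free = -dq)),
               rate_law = list(base_rate = h2r(p$t_half_tgfb1) / dq,
                               token_factor = "TGFB1_free"),
               group = "tgfb1_clearance"))

  attr(rules, "family") <- family
  rules
}

#' Initial system state
#'
#' `n_init_qhsc` quiescent cells (free binding site, membrane receptor,
#' counter at 0), no TGFbeta1 and the baseline collagen amount in the
#' low-remodeling pool.
#'
#' @param params An `hsc_parameters` table.
#' @return An [system_state()] at clock 0.
#' @export
initial_state <- function(params = default_parameters()) {
  agents <- agent_state("qHSC")[rep(1, params$n_init_qhsc), ]
  rownames(agents) <- NULL
  system_state(agents,
               token_pool(COL1_remodeling_low = params$col1_baseline))
}
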