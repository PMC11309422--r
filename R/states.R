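# Site vocabularies and the class encoding shared by the R and C++ layers.
#
# An agent configuration class encodes the complete site vector
# (cell state, TGFB1 binding site, receptor site, counter value) as a single
# 0-based integer; all agents in a class are exchangeable, so the simulator
# tracks counts per class rather than individual agents.

#' Site vocabularies of the HSC agent schema
#'
#' Constants naming the categorical sites of the single agent type and the
#' four token pools. The cell can be quiescent (`qHSC`), activated (`aHSC`),
#' a myofibroblast (`MFB`), inactivated (`iHSC`), reactivated (`react_HSC`),
#' a reactivated myofibroblast (`react_MFB`) or committed to elimination
#' (`apop_sene_MFB`). The differentiation counter runs from 0 to
#' `hsc_n_steps()` (14) and is paired with a control counter so that the two
#' always sum to 14.
#'
#' @return A character vector of admissible values.
#' @export
hsc_cell_states <- function() {
  c("qHSC", "aHSC", "MFB", "iHSC", "react_HSC", "react_MFB", "apop_sene_MFB")
}

#' @rdname hsc_cell_states
#' @export
hsc_binding_states <- function() c("free", "bound")

#' @rdname hsc_cell_states
#' @export
hsc_receptor_states <- function() c("membrane", "internalized", "degraded")

#' @rdname hsc_cell_states
#' @export
hsc_token_names <- function() {
  c("TGFB1_free", "TGFB1_bound", "COL1_remodeling_high", "COL1_remodeling_low")
}

#' @rdname hsc_cell_states
#' @export
hsc_n_steps <- function() 14L

# cell states whose carriers express alpha-smooth-muscle actin
.ALPHA_SMA_STATES <- c("aHSC", "MFB", "react_HSC", "react_MFB")

# number of configuration classes: 7 states x 2 binding x 3 receptor x 15 steps
.N_CLASSES <- 7L * 2L * 3L * 15L

# 0-based class index from 1-based site indices
.class_index <- function(state_i, bind_i, rec_i, step) {
  (((state_i - 1L) * 2L + (bind_i - 1L)) * 3L + (rec_i - 1L)) * 15L + step
}

# decode a 0-based class index into a data.frame of site values
.class_decode <- function(idx) {
  step <- idx %% 15L
  r <- idx %/% 15L
  rec <- r %% 3L
  r <- r %/% 3L
  bind <- r %% 2L
  state <- r %/% 2L
  data.frame(
    cell_state = hsc_cell_states()[state + 1L],
    tgfb1_binding = hsc_binding_states()[bind + 1L],
    tgfbr = hsc_receptor_states()[rec + 1L],
    intermediate_step = step,
    control_counter = 14L - step,
    stringsAsFactors = FALSE
  )
}

# 0-based class indices whose cell state is in `states`
.classes_of_states <- function(states) {
  state_i <- match(states, hsc_cell_states())
  idx <- integer(0)
  for (s in state_i) {
    base <- (s - 1L) * 90L
    idx <- c(idx, base + 0:89)
  }
  idx
}

.alpha_sma_classes <- function() .classes_of_states(.ALPHA_SMA_STATES)

# all states except cells already committed to apoptosis/senescence count as
# living for the purpose of per-cell perturbation doses
.living_classes <- function() {
  .classes_of_states(setdiff(hsc_cell_states(), "apop_sene_MFB"))
}
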