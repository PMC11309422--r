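# Small rule sets and states used across tests; everything is built in code.

# pure token decay: d|X|/dt = -k|X|, one unit per event
decay_rules <- function(k = 0.5, token = "TGFB1_free") {
  td <- setNames(-1, token)
  list(hsc_rule("decay", guard = NULL, effect = list(tokens = td),
                rate_law = list(base_rate = k, token_factor = token)))
}

# zeroth-order birth of quiescent cells + per-agent death
birth_death_rules <- function(b = 5, d = 0.1) {
  list(
    hsc_rule("birth", guard = NULL,
             effect = list(create = agent_state("qHSC")),
             rate_law = list(base_rate = b)),
    hsc_rule("death", guard = list(cell_state = "qHSC"),
             effect = list(delete = TRUE),
             rate_law = list(base_rate = d)))
}

# a population of n quiescent cells
qhsc_state <- function(n, tokens = token_pool()) {
  a <- agent_state("qHSC")[rep(1, n), ]
  rownames(a) <- NULL
  system_state(a, tokens)
}

# rule list indexed by id, for picking single rules out of a built model
rule_by_id <- function(rules, id) {
  ids <- vapply(rules, `[[`, "", "id")
  rules[[match(id, ids)]]
}

# fast parameter table for model-level tests (dynamics do not need to be
# calibrated here, only structurally correct)
test_params <- function(family = "reactMFB-with-inactivation", ...) {
  p <- default_parameters(family)
  ov <- list(...)
  for (n in names(ov)) p[[n]] <- ov[[n]]
  p
}
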