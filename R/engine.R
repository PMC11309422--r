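# In-memory contract of the simulator: domain types, the reference (pure R)
# implementations of propensity evaluation and single-event dynamics, and the
# compiled fast path used by simulate().

#' Construct a single HSC agent
#'
#' An agent carries a categorical cell state, a TGFbeta1 binding site, a
#' receptor trafficking site and a bounded counter pair. The two counters
#' (`intermediate_step`, `control_counter`) always sum to 14; the pairing is
#' the standard rule-based-modelling workaround for the missing upper-bound
#' test on a single counter. Quiescent cells sit at step 0.
#'
#' @param cell_state One of [hsc_cell_states()].
#' @param tgfb1_binding `"free"` or `"bound"`.
#' @param tgfbr `"membrane"`, `"internalized"` or `"degraded"`.
#' @param intermediate_step Integer in 0..14.
#' @param control_counter Integer in 0..14; defaults to `14 - intermediate_step`.
#' @return A one-row data.frame of class `hsc_agent`.
#' @export
agent_state <- function(cell_state = "qHSC", tgfb1_binding = "free",
                        tgfbr = "membrane", intermediate_step = 0L,
                        control_counter = 14L - as.integer(intermediate_step)) {
  cell_state <- match.arg(cell_state, hsc_cell_states())
  tgfb1_binding <- match.arg(tgfb1_binding, hsc_binding_states())
  tgfbr <- match.arg(tgfbr, hsc_receptor_states())
  a <- data.frame(
    cell_state = cell_state, tgfb1_binding = tgfb1_binding, tgfbr = tgfbr,
    intermediate_step = as.integer(intermediate_step),
    control_counter = as.integer(control_counter),
    stringsAsFactors = FALSE
  )
  class(a) <- c("hsc_agent", class(a))
  a
}

#' Construct a token pool
#'
#' The four tokens are continuous non-negative global quantities: free and
#' receptor-bound TGFbeta1 (in molecule-per-cell-equivalent units) and the
#' high- and low-remodeling collagen-I pools (arbitrary units).
#'
#' @param ... Named amounts; unnamed tokens default to 0.
#' @return A named numeric vector of class `hsc_tokens`.
#' @export
token_pool <- function(...) {
  amounts <- c(...)
  pool <- setNames(numeric(4), hsc_token_names())
  if (length(amounts)) {
    bad <- setdiff(names(amounts), hsc_token_names())
    if (length(bad)) stop("unknown token name(s): ", paste(bad, collapse = ", "))
    pool[names(amounts)] <- as.numeric(amounts)
  }
  class(pool) <- "hsc_tokens"
  pool
}

#' Construct a system state
#'
#' @param agents A data.frame of agents (rows as produced by [agent_state()],
#'   possibly `rbind`-ed) or a list of agents.
#' @param tokens A token pool from [token_pool()].
#' @param clock Simulation time in hours.
#' @return An object of class `hsc_state`.
#' @export
system_state <- function(agents, tokens = token_pool(), clock = 0) {
  if (is.list(agents) && !is.data.frame(agents)) {
    agents <- do.call(rbind, agents)
  }
  stopifnot(is.data.frame(agents) || is.null(agents))
  if (is.null(agents)) agents <- agent_state()[0, ]
  st <- list(agents = agents, tokens = tokens, clock = clock)
  class(st) <- "hsc_state"
  st
}

#' @export
print.hsc_state <- function(x, ...) {
  cat("<hsc_state> t =", x$clock, "h;", nrow(x$agents), "agents\n")
  if (nrow(x$agents)) print(table(x$agents$cell_state))
  cat("tokens:", paste(names(unclass(x$tokens)),
                       signif(unclass(x$tokens), 4),
                       sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' Construct a timed perturbation
#'
#' A perturbation adds token amounts at an exact time; amounts flagged
#' `per_cell` are multiplied by the number of living agents (all cells not
#' committed to apoptosis/senescence) at the moment the perturbation fires.
#'
#' @param time Hours.
#' @param token_additions Named numeric vector of amounts (token names).
#' @param per_cell Interpret amounts as molecules per living cell.
#' @return An object of class `hsc_perturbation`.
#' @export
perturbation <- function(time, token_additions, per_cell = FALSE) {
  stopifnot(is.numeric(time), length(time) == 1, time >= 0)
  bad <- setdiff(names(token_additions), hsc_token_names())
  if (length(bad)) stop("unknown token name(s): ", paste(bad, collapse = ", "))
  if (any(token_additions < 0)) stop("perturbation amounts must be >= 0")
  p <- list(time = time, token_additions = token_additions,
            per_cell = isTRUE(per_cell))
  class(p) <- "hsc_perturbation"
  p
}

# ---------------------------------------------------------------------------
# Rules
# ---------------------------------------------------------------------------

#' Construct a rule
#'
#' A rule couples a guard over agent sites and counters (absent for agent-free
#' token rules and creation rules) with an atomic effect (site writes, counter
#' moves, agent creation or deletion, token deltas) and a mass-action rate
#' law. The propensity of a rule is
#' `base_rate * matches * token_factor * population_factor`, where `matches`
#' is the number of agents satisfying the guard (1 for agent-free rules), or
#' the sum of their `intermediate_step` values when `counter_factor` is set.
#' A rule whose firing would drive any token negative has propensity zero.
#'
#' @param id Rule identifier (string).
#' @param guard `NULL` for agent-free rules, else a list with optional
#'   entries `cell_state`, `tgfb1_binding`, `tgfbr` (each a value or vector of
#'   admissible values) and `step_min`/`step_max` (counter bounds, inclusive).
#' @param effect List with optional entries `cell_state`, `tgfb1_binding`,
#'   `tgfbr` (site writes), `step_delta` (counter increment, the control
#'   counter moves oppositely), `step_set` (absolute counter write),
#'   `delete = TRUE` (remove the agent), `create` (an [agent_state()] template
#'   added to the system), `daughter = TRUE` (duplicate the matched agent,
#'   copying every site except the receptor, which starts at the membrane,
#'   and the binding site, which starts free), and `tokens` (named deltas).
#' @param rate_law List with `base_rate` (per hour) and optional
#'   `token_factor` (token name), `counter_factor` (logical),
#'   `population_factor` (`"alpha_sma"`).
#' @param group Optional label used by the model builder.
#' @return An object of class `hsc_rule`.
#' @export
hsc_rule <- function(id, guard = NULL, effect = list(),
                     rate_law = list(base_rate = 0), group = NA_character_) {
  stopifnot(is.character(id), length(id) == 1)
  if (!is.null(guard)) {
    stopifnot(is.list(guard))
    unknown <- setdiff(names(guard),
                       c("cell_state", "tgfb1_binding", "tgfbr",
                         "step_min", "step_max"))
    if (length(unknown)) stop("unknown guard field(s): ",
                              paste(unknown, collapse = ", "))
    if (!is.null(guard$cell_state) &&
        !all(guard$cell_state %in% hsc_cell_states()))
      stop("unknown cell state in guard of rule ", id)
    if (!is.null(guard$tgfb1_binding) &&
        !all(guard$tgfb1_binding %in% hsc_binding_states()))
      stop("bad binding guard in rule ", id)
    if (!is.null(guard$tgfbr) && !all(guard$tgfbr %in% hsc_receptor_states()))
      stop("bad receptor guard in rule ", id)
  }
  unknown <- setdiff(names(effect),
                     c("cell_state", "tgfb1_binding", "tgfbr", "step_delta",
                       "step_set", "delete", "create", "daughter", "tokens"))
  if (length(unknown)) stop("unknown effect field(s): ",
                            paste(unknown, collapse = ", "))
  if (!is.null(effect$tokens)) {
    bad <- setdiff(names(effect$tokens), hsc_token_names())
    if (length(bad)) stop("unknown token in effect of rule ", id, ": ",
                          paste(bad, collapse = ", "))
  }
  stopifnot(is.numeric(rate_law$base_rate), rate_law$base_rate >= 0,
            is.finite(rate_law$base_rate))
  if (!is.null(rate_law$token_factor) &&
      !rate_law$token_factor %in% hsc_token_names())
    stop("unknown token_factor in rule ", id, ": ", rate_law$token_factor)
  if (!is.null(rate_law$population_factor) &&
      !identical(rate_law$population_factor, "alpha_sma"))
    stop("unknown population_factor in rule ", id)
  if (is.null(guard) && (isTRUE(effect$delete) || isTRUE(effect$daughter) ||
                         !is.null(effect$cell_state)))
    stop("agent-free rule ", id, " cannot modify or delete an agent")
  r <- list(id = id, guard = guard, effect = effect, rate_law = rate_law,
            group = group)
  class(r) <- "hsc_rule"
  r
}

#' @export
print.hsc_rule <- function(x, ...) {
  cat("<hsc_rule>", x$id, if (!is.na(x$group)) paste0("[", x$group, "]"),
      "@", x$rate_law$base_rate, "/h\n")
  invisible(x)
}

# does one agent row satisfy a rule guard?
.guard_matches <- function(guard, agents) {
  if (is.null(guard)) return(rep(FALSE, nrow(agents)))
  ok <- rep(TRUE, nrow(agents))
  if (!is.null(guard$cell_state))
    ok <- ok & agents$cell_state %in% guard$cell_state
  if (!is.null(guard$tgfb1_binding))
    ok <- ok & agents$tgfb1_binding %in% guard$tgfb1_binding
  if (!is.null(guard$tgfbr)) ok <- ok & agents$tgfbr %in% guard$tgfbr
  if (!is.null(guard$step_min))
    ok <- ok & agents$intermediate_step >= guard$step_min
  if (!is.null(guard$step_max))
    ok <- ok & agents$intermediate_step <= guard$step_max
  ok
}

# per-agent propensity weights for a rule (0 for non-matching agents)
.agent_weights <- function(rule, state) {
  if (is.null(rule$guard)) return(numeric(0))
  m <- .guard_matches(rule$guard, state$agents)
  w <- as.numeric(m)
  if (isTRUE(rule$rate_law$counter_factor))
    w <- w * state$agents$intermediate_step
  w
}

.token_requirement <- function(rule) {
  td <- rule$effect$tokens
  if (is.null(td)) return(NULL)
  req <- -pmin(td, 0)
  req[req > 0]
}

#' Propensity of a rule in a state
#'
#' Reference (pure R) implementation of the rate law; the compiled simulator
#' computes the same quantity incrementally. Returns 0 when no agent matches,
#' when a multiplying token is exhausted, or when a required token amount is
#' unavailable.
#'
#' @param rule An [hsc_rule()].
#' @param state An [system_state()].
#' @return A non-negative rate (per hour).
#' @export
propensity <- function(rule, state) {
  req <- .token_requirement(rule)
  if (!is.null(req) && any(unclass(state$tokens)[names(req)] < req)) return(0)
  if (is.null(rule$guard)) {
    m <- 1
  } else {
    m <- sum(.agent_weights(rule, state))
    if (m <= 0) return(0)
  }
  p <- rule$rate_law$base_rate * m
  if (!is.null(rule$rate_law$token_factor))
    p <- p * unclass(state$tokens)[[rule$rate_law$token_factor]]
  if (identical(rule$rate_law$population_factor, "alpha_sma"))
    p <- p * sum(state$agents$cell_state %in% .ALPHA_SMA_STATES)
  max(p, 0)
}

#' Draw the next stochastic event (direct method)
#'
#' Samples the waiting time from an exponential with the total propensity as
#' rate, picks a rule with probability proportional to its propensity, and a
#' target agent with probability proportional to its per-agent weight.
#' Uses R's RNG stream (seed with [set.seed()]). With zero total propensity
#' the waiting time is infinite and no rule is returned.
#'
#' @param state An [system_state()].
#' @param rules List of rules.
#' @return List with `waiting_time` (hours), `rule` (or `NULL`) and
#'   `agent` (row index in `state$agents`, or `NA`).
#' @export
draw_next_event <- function(state, rules) {
  stopifnot(length(rules) >= 1)
  p <- vapply(rules, propensity, numeric(1), state = state)
  total <- sum(p)
  if (total <= 0) {
    return(list(waiting_time = Inf, rule = NULL, agent = NA_integer_))
  }
  wt <- rexp(1, rate = total)
  ri <- sample.int(length(rules), 1, prob = p)
  rule <- rules[[ri]]
  agent <- NA_integer_
  if (!is.null(rule$guard)) {
    w <- .agent_weights(rule, state)
    agent <- sample.int(nrow(state$agents), 1, prob = w)
  }
  list(waiting_time = wt, rule = rule, agent = agent)
}

#' Apply a rule effect to a state
#'
#' Applies the atomic effect of `rule` to the agent at row `agent` (ignored
#' for agent-free rules) and to the token pool. The rule guard and the token
#' requirement must hold; a violation is an internal logic error because
#' [draw_next_event()] never proposes an inapplicable event.
#'
#' @inheritParams draw_next_event
#' @param rule The rule to fire.
#' @param agent Row index of the target agent (NA for agent-free rules).
#' @return The updated `hsc_state`.
#' @export
apply_event <- function(state, rule, agent = NA_integer_) {
  eff <- rule$effect
  agents <- state$agents
  tokens <- unclass(state$tokens)
  if (!is.null(rule$guard)) {
    stopifnot(!is.na(agent), agent >= 1, agent <= nrow(agents))
    if (!.guard_matches(rule$guard, agents[agent, , drop = FALSE]))
      stop("internal logic error: guard of rule ", rule$id,
           " violated by target agent")
    if (isTRUE(eff$daughter)) {
      d <- agents[agent, , drop = FALSE]
      d$tgfb1_binding <- "free"
      d$tgfbr <- "membrane"
      agents <- rbind(agents, d)
    }
    if (isTRUE(eff$delete)) {
      agents <- agents[-agent, , drop = FALSE]
    } else {
      if (!is.null(eff$step_set)) {
        agents$intermediate_step[agent] <- as.integer(eff$step_set)
      } else if (!is.null(eff$step_delta)) {
        agents$intermediate_step[agent] <-
          agents$intermediate_step[agent] + as.integer(eff$step_delta)
      }
      agents$control_counter[agent] <- 14L - agents$intermediate_step[agent]
      if (!is.null(eff$cell_state)) agents$cell_state[agent] <- eff$cell_state
      if (!is.null(eff$tgfb1_binding))
        agents$tgfb1_binding[agent] <- eff$tgfb1_binding
      if (!is.null(eff$tgfbr)) agents$tgfbr[agent] <- eff$tgfbr
    }
  }
  if (!is.null(eff$create)) agents <- rbind(agents, eff$create)
  if (!is.null(eff$tokens)) {
    req <- .token_requirement(rule)
    if (!is.null(req) && any(tokens[names(req)] < req))
      stop("internal logic error: token requirement of rule ", rule$id,
           " unmet")
    tokens[names(eff$tokens)] <- tokens[names(eff$tokens)] + eff$tokens
  }
  out <- system_state(agents, do.call(token_pool, as.list(tokens)),
                      clock = state$clock)
  viol <- check_invariants(out)
  if (length(viol))
    stop("internal logic error after rule ", rule$id, ": ",
         paste(viol, collapse = "; "))
  out
}

#' List invariant violations of a state
#'
#' Checks counter pairing (`intermediate_step + control_counter == 14`),
#' counter bounds, the quiescent-cell convention (`qHSC` implies step 0) and
#' token non-negativity. An empty character vector means the state is valid.
#'
#' @param state An [system_state()].
#' @return Character vector of violation messages.
#' @export
check_invariants <- function(state) {
  viol <- character(0)
  a <- state$agents
  if (nrow(a)) {
    bad <- a$intermediate_step + a$control_counter != 14L
    if (any(bad))
      viol <- c(viol, sprintf(
        "agent %d: counters sum to %d, not 14", which(bad),
        (a$intermediate_step + a$control_counter)[bad]))
    oob <- a$intermediate_step < 0L | a$intermediate_step > 14L
    if (any(oob))
      viol <- c(viol, sprintf("agent %d: counter out of 0..14", which(oob)))
    q <- a$cell_state == "qHSC" & a$intermediate_step != 0L
    if (any(q))
      viol <- c(viol, sprintf("agent %d: quiescent cell at step > 0", which(q)))
  }
  tok <- unclass(state$tokens)
  if (any(tok < 0))
    viol <- c(viol, sprintf("token %s negative (%g)",
                            names(tok)[tok < 0], tok[tok < 0]))
  viol
}

# ---------------------------------------------------------------------------
# Compilation to the class-count representation
# ---------------------------------------------------------------------------

# enumerate the 0-based classes matching a guard
.guard_classes <- function(guard) {
  states <- guard$cell_state %||% hsc_cell_states()
  binds <- guard$tgfb1_binding %||% hsc_binding_states()
  recs <- guard$tgfbr %||% hsc_receptor_states()
  smin <- guard$step_min %||% 0L
  smax <- guard$step_max %||% 14L
  g <- expand.grid(step = smin:smax,
                   rec = match(recs, hsc_receptor_states()),
                   bind = match(binds, hsc_binding_states()),
                   state = match(states, hsc_cell_states()))
  # quiescent cells only exist at step 0; drop the structurally invalid
  # classes from the guard expansion
  g <- g[!(g$state == 1L & g$step != 0L), , drop = FALSE]
  .class_index(g$state, g$bind, g$rec, g$step)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# apply a rule effect to a decoded class; returns the destination class
.effect_class <- function(eff, dec) {
  step <- dec$intermediate_step
  if (!is.null(eff$step_set)) step <- as.integer(eff$step_set)
  else if (!is.null(eff$step_delta)) step <- step + as.integer(eff$step_delta)
  state <- eff$cell_state %||% dec$cell_state
  bind <- eff$tgfb1_binding %||% dec$tgfb1_binding
  rec <- eff$tgfbr %||% dec$tgfbr
  if (step < 0L || step > 14L)
    stop("effect drives counter out of 0..14 (guard too permissive)")
  if (state == "qHSC" && step != 0L)
    stop("effect produces a quiescent cell at step > 0")
  .class_index(match(state, hsc_cell_states()),
               match(bind, hsc_binding_states()),
               match(rec, hsc_receptor_states()), step)
}

# compile a rule list for the C++ core
.compile_rules <- function(rules) {
  lapply(rules, function(r) {
    td <- setNames(numeric(4), hsc_token_names())
    if (!is.null(r$effect$tokens)) td[names(r$effect$tokens)] <- r$effect$tokens
    tf <- if (is.null(r$rate_law$token_factor)) -1L else
      match(r$rate_law$token_factor, hsc_token_names()) - 1L
    pf <- if (identical(r$rate_law$population_factor, "alpha_sma")) 1L else 0L
    if (is.null(r$guard)) {
      create_cls <- -1L
      if (!is.null(r$effect$create)) {
        cr <- r$effect$create
        create_cls <- .class_index(match(cr$cell_state, hsc_cell_states()),
                                   match(cr$tgfb1_binding, hsc_binding_states()),
                                   match(cr$tgfbr, hsc_receptor_states()),
                                   cr$intermediate_step)
      }
      return(list(cls = integer(0), w = numeric(0), dst = integer(0),
                  dau = integer(0), create_cls = create_cls,
                  base = r$rate_law$base_rate, tf = tf, pf = pf, td = td))
    }
    cls <- .guard_classes(r$guard)
    dec <- .class_decode(cls)
    w <- if (isTRUE(r$rate_law$counter_factor))
      as.numeric(dec$intermediate_step) else rep(1, length(cls))
    if (isTRUE(r$effect$delete)) {
      dst <- rep(-1L, length(cls))
    } else {
      dst <- vapply(seq_along(cls), function(i)
        .effect_class(r$effect, dec[i, , drop = FALSE]), integer(1))
    }
    dau <- rep(-1L, length(cls))
    if (isTRUE(r$effect$daughter)) {
      # daughter copies state and counter, receptor at membrane, site free
      dau <- .class_index(match(dec$cell_state, hsc_cell_states()),
                          1L, 1L, dec$intermediate_step)
    }
    if (!is.null(r$effect$create))
      stop("rule ", r$id, ": create is only supported for agent-free rules")
    list(cls = as.integer(cls), w = as.numeric(w), dst = as.integer(dst),
         dau = as.integer(dau), create_cls = -1L,
         base = r$rate_law$base_rate, tf = tf, pf = pf, td = td)
  })
}

# counts per class from an agent data.frame
.counts_from_agents <- function(agents) {
  counts <- numeric(.N_CLASSES)
  if (nrow(agents)) {
    idx <- .class_index(match(agents$cell_state, hsc_cell_states()),
                        match(agents$tgfb1_binding, hsc_binding_states()),
                        match(agents$tgfbr, hsc_receptor_states()),
                        agents$intermediate_step) + 1L
    tab <- table(idx)
    counts[as.integer(names(tab))] <- as.numeric(tab)
  }
  counts
}

# flatten a protocol (or list of perturbations) into the matrix expected by
# the C++ core: columns time, token (0-based), amount, per_cell
.pert_matrix <- function(protocol, horizon) {
  events <- if (is.null(protocol)) list()
  else if (inherits(protocol, "hsc_protocol")) protocol$events
  else if (inherits(protocol, "hsc_perturbation")) list(protocol)
  else protocol
  if (!length(events)) return(matrix(numeric(0), ncol = 4))
  times <- vapply(events, function(e) e$time, numeric(1))
  if (any(diff(times) <= 0))
    stop("perturbation times must be strictly increasing")
  rows <- do.call(rbind, lapply(events, function(e) {
    cbind(e$time, match(names(e$token_additions), hsc_token_names()) - 1L,
          as.numeric(e$token_additions), as.numeric(isTRUE(e$per_cell)))
  }))
  rows[rows[, 1] <= horizon, , drop = FALSE]
}

# ---------------------------------------------------------------------------
# Simulation
# ---------------------------------------------------------------------------

#' Run one exact stochastic simulation
#'
#' Executes the Gillespie direct method over the rule set, interleaving
#' scheduled perturbations (applied at exactly their time, before any sample
#' taken at the same instant) with reaction events, and samples the state at
#' each point of the record grid. The run is driven by a private
#' counter-based RNG stream: an identical `(rules, initial, protocol, seed)`
#' quadruple reproduces the event sequence bit for bit.
#'
#' @param rules List of [hsc_rule()] objects.
#' @param initial An [system_state()].
#' @param protocol `NULL`, a [stimulation_protocol()], or a list of
#'   [perturbation()]s.
#' @param horizon End time (hours).
#' @param record_grid Strictly increasing sample times within `[0, horizon]`;
#'   defaults to every 12 h.
#' @param seed Non-negative integer seed for the private stream.
#' @param debug_checks Verify token/count non-negativity after every event.
#' @return A data.frame of class `hsc_timeseries` with one row per grid time:
#'   `time` (hours), the seven cell-state counts, the four token amounts and
#'   the derived `alpha_sma` and `col1_total` columns. Attributes carry the
#'   seed, event count, final state and the perturbation log.
#' @export
simulate_hsc <- function(rules, initial, protocol = NULL, horizon,
                         record_grid = seq(0, horizon, by = 12),
                         seed = 1, debug_checks = FALSE) {
  stopifnot(length(rules) >= 1, inherits(initial, "hsc_state"),
            is.numeric(horizon), horizon >= 0)
  record_grid <- as.numeric(record_grid)
  if (length(record_grid) == 0) record_grid <- 0
  if (any(diff(record_grid) <= 0))
    stop("record grid times must be strictly increasing")
  if (min(record_grid) < 0 || max(record_grid) > horizon)
    stop("record grid must lie within [0, horizon]")
  if (!is.numeric(seed) || length(seed) != 1 || seed < 0 || seed != floor(seed))
    stop("seed must be a single non-negative integer")

  compiled <- attr(rules, "compiled") %||% .compile_rules(rules)
  counts0 <- .counts_from_agents(initial$agents)
  tokens0 <- as.numeric(unclass(initial$tokens))
  if (any(tokens0 < 0)) stop("initial token amounts must be non-negative")
  pm <- .pert_matrix(protocol, horizon)

  res <- .sim_core(compiled, counts0, tokens0, horizon, record_grid, pm,
                   as.numeric(seed), as.integer(.alpha_sma_classes()),
                   as.integer(.living_classes()), debug_checks)

  samples <- res$samples
  colnames(samples) <- c("time", hsc_cell_states(), hsc_token_names())
  ts <- as.data.frame(samples)
  ts$alpha_sma <- ts$aHSC + ts$MFB + ts$react_HSC + ts$react_MFB
  ts$col1_total <- ts$COL1_remodeling_high + ts$COL1_remodeling_low
  class(ts) <- c("hsc_timeseries", class(ts))
  attr(ts, "seed") <- seed
  attr(ts, "n_events") <- res$n_events
  attr(ts, "final_counts") <- res$final_counts
  attr(ts, "final_tokens") <- setNames(res$final_tokens, hsc_token_names())
  attr(ts, "pert_applied") <- if (nrow(pm)) cbind(pm[, 1:2, drop = FALSE],
                                                  applied = res$pert_applied)
  else NULL
  attr(ts, "protocol") <- if (inherits(protocol, "hsc_protocol"))
    protocol$name else NA_character_
  ts
}

#' Run independent replicates
#'
#' Replicate `i` uses seed `base_seed + i - 1` on its own private stream, so
#' replicates are independent and the whole batch is reproducible and
#' order-deterministic.
#'
#' @inheritParams simulate_hsc
#' @param n_replicates Number of replicates (>= 1).
#' @param base_seed Seed of the first replicate.
#' @return A list of `hsc_timeseries`.
#' @export
run_replicates <- function(rules, initial, protocol = NULL, horizon,
                           record_grid = seq(0, horizon, by = 12),
                           n_replicates, base_seed = 1) {
  stopifnot(n_replicates >= 1)
  # compile once for the whole batch
  if (is.null(attr(rules, "compiled")))
    attr(rules, "compiled") <- .compile_rules(rules)
  lapply(seq_len(n_replicates), function(i) {
    simulate_hsc(rules, initial, protocol, horizon, record_grid,
                 seed = base_seed + i - 1)
  })
}
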