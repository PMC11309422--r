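# Engine semantics: propensities, event drawing, effects, invariants,
# simulation against closed-form oracles.

test_that("propensity follows the mass-action rate law", {
  death <- birth_death_rules(d = 0.1)[[2]]
  # no matching agent
  expect_equal(propensity(death, system_state(NULL)), 0)
  # 10 matching agents, base 0.1/h, no factors: brute-force sum of per-agent
  # propensities = 10 * 0.1
  st10 <- qhsc_state(10)
  per_agent <- vapply(1:10, function(i)
    propensity(death, system_state(st10$agents[i, , drop = FALSE])),
    numeric(1))
  expect_equal(propensity(death, st10), 1.0)
  expect_equal(sum(per_agent), propensity(death, st10))
  # token factor of an exhausted pool
  bind <- hsc_rule("bind", guard = list(cell_state = "qHSC",
                                        tgfb1_binding = "free"),
                   effect = list(tgfb1_binding = "bound",
                                 tokens = c(TGFB1_free = -1, TGFB1_bound = 1)),
                   rate_law = list(base_rate = 1, token_factor = "TGFB1_free"))
  expect_equal(propensity(bind, qhsc_state(5)), 0)
  expect_equal(propensity(bind, qhsc_state(5, token_pool(TGFB1_free = 20))),
               100)
  # counter factor replaces the match count by the counter sum
  prod <- hsc_rule("prod", guard = list(cell_state = "aHSC"),
                   effect = list(tokens = c(COL1_remodeling_high = 1)),
                   rate_law = list(base_rate = 2, counter_factor = TRUE))
  ag <- rbind(agent_state("aHSC", intermediate_step = 3),
              agent_state("aHSC", intermediate_step = 5))
  expect_equal(propensity(prod, system_state(ag)), 2 * (3 + 5))
  # unmet token requirement silences the rule even with positive factor
  deg <- hsc_rule("deg", guard = NULL,
                  effect = list(tokens = c(COL1_remodeling_high = -5)),
                  rate_law = list(base_rate = 1,
                                  token_factor = "COL1_remodeling_high"))
  expect_equal(propensity(deg, system_state(
    NULL, token_pool(COL1_remodeling_high = 3))), 0)
})

test_that("reference propensities agree with the compiled engine", {
  p <- test_params()
  rules <- build_rules(params = p)
  set.seed(5)
  # random mixed state
  ag <- do.call(rbind, lapply(1:40, function(i) {
    s <- sample(hsc_cell_states(), 1)
    step <- if (s == "qHSC") 0L else sample(0:14, 1)
    agent_state(s, sample(hsc_binding_states(), 1),
                sample(hsc_receptor_states(), 1), step)
  }))
  st <- system_state(ag, token_pool(TGFB1_free = 321, TGFB1_bound = 17,
                                    COL1_remodeling_high = 40.5,
                                    COL1_remodeling_low = 99))
  p_r <- vapply(rules, propensity, numeric(1), state = st)
  p_cpp <- hscsim:::.sim_propensities(
    hscsim:::.compile_rules(rules),
    hscsim:::.counts_from_agents(st$agents),
    as.numeric(unclass(st$tokens)),
    as.integer(hscsim:::.alpha_sma_classes()),
    as.integer(hscsim:::.living_classes()))
  expect_equal(p_cpp, p_r, tolerance = 1e-12)
})

test_that("draw_next_event samples waiting times and rules correctly", {
  # zero total propensity: infinite waiting time, no rule
  empty <- draw_next_event(system_state(NULL), birth_death_rules(b = 0, d = 1))
  expect_identical(empty$waiting_time, Inf)
  expect_null(empty$rule)

  # single pure-death rule with N agents: waiting time ~ Exp(k N)
  st <- qhsc_state(20)
  death <- list(hsc_rule("death", guard = list(cell_state = "qHSC"),
                         effect = list(delete = TRUE),
                         rate_law = list(base_rate = 0.25)))
  set.seed(1)
  wt <- replicate(1e4, draw_next_event(st, death)$waiting_time)
  mu <- 1 / (0.25 * 20)
  expect_lt(abs(mean(wt) - mu), 3 * mu / sqrt(1e4))

  # two rules with propensities 3 and 1: first picked about 75% of the time
  two <- list(
    hsc_rule("a", guard = NULL, effect = list(tokens = c(TGFB1_free = 1)),
             rate_law = list(base_rate = 3)),
    hsc_rule("b", guard = NULL, effect = list(tokens = c(TGFB1_bound = 1)),
             rate_law = list(base_rate = 1)))
  set.seed(2)
  picks <- replicate(1e4, draw_next_event(system_state(NULL), two)$rule$id)
  phat <- mean(picks == "a")
  expect_lt(abs(phat - 0.75), 3 * sqrt(0.75 * 0.25 / 1e4))
})

test_that("apply_event implements the rewrite semantics atomically", {
  # deletion shrinks the population by one
  st <- qhsc_state(5)
  death <- birth_death_rules()[[2]]
  expect_equal(nrow(apply_event(st, death, 3)$agents), 4)

  # activation-step effect: (step 3, control 11) -> (step 4, control 10)
  rules <- build_rules(params = test_params())
  step_rule <- rule_by_id(rules, "step_ahsc")
  st2 <- system_state(agent_state("aHSC", intermediate_step = 3))
  expect_equal(st2$agents$control_counter, 11)
  out <- apply_event(st2, step_rule, 1)
  expect_equal(out$agents$intermediate_step, 4)
  expect_equal(out$agents$control_counter, 10)

  # binding effect: one token moves free -> bound, site binds, receptor
  # internalizes
  bind_rule <- rule_by_id(rules, "bind_qHSC")
  st3 <- qhsc_state(1, token_pool(TGFB1_free = 10))
  out3 <- apply_event(st3, bind_rule, 1)
  expect_equal(unclass(out3$tokens)[["TGFB1_free"]], 9)
  expect_equal(unclass(out3$tokens)[["TGFB1_bound"]], 1)
  expect_equal(out3$agents$tgfb1_binding, "bound")
  expect_equal(out3$agents$tgfbr, "internalized")

  # guard violation is an internal logic error
  expect_error(apply_event(st3, step_rule, 1), "guard")

  # daughter copies sites except receptor and binding
  prolif <- rule_by_id(rules, "prolif_aHSC_tgfb_s4")
  st4 <- system_state(agent_state("aHSC", "bound", "internalized", 4),
                      token_pool(TGFB1_bound = 1))
  out4 <- apply_event(st4, prolif, 1)
  expect_equal(nrow(out4$agents), 2)
  daughter <- out4$agents[2, ]
  expect_equal(daughter$cell_state, "aHSC")
  expect_equal(daughter$intermediate_step, 4)
  expect_equal(daughter$tgfbr, "membrane")
  expect_equal(daughter$tgfb1_binding, "free")
})

test_that("check_invariants flags broken states", {
  expect_length(check_invariants(initial_state(test_params())), 0)
  bad_counter <- system_state(agent_state("aHSC", intermediate_step = 5,
                                          control_counter = 5))
  expect_match(check_invariants(bad_counter), "counters sum", all = FALSE)
  bad_token <- system_state(NULL)
  bad_token$tokens[["COL1_remodeling_high"]] <- -1
  expect_match(check_invariants(bad_token), "negative", all = FALSE)
})

test_that("simulate reproduces closed-form kinetics", {
  # horizon 0: only the initial sample
  st <- qhsc_state(3, token_pool(TGFB1_free = 7))
  ts0 <- simulate_hsc(decay_rules(), st, NULL, horizon = 0, record_grid = 0,
                      seed = 1)
  expect_equal(nrow(ts0), 1)
  expect_equal(ts0$TGFB1_free, 7)
  expect_equal(ts0$qHSC, 3)

  # linear token decay: mean of 50 replicates within 5% of 1000 exp(-kt)
  st1 <- system_state(NULL, token_pool(TGFB1_free = 1000))
  reps <- run_replicates(decay_rules(k = 0.3), st1, NULL, horizon = 8,
                         record_grid = c(2, 5, 8), n_replicates = 50,
                         base_seed = 10)
  agg <- aggregate_replicates(reps)
  expected <- 1000 * exp(-0.3 * c(2, 5, 8))
  expect_true(all(abs(agg$TGFB1_free_mean - expected) / expected < 0.05))

  # birth-death: long-run time-average within 5% of b/d
  ts2 <- simulate_hsc(birth_death_rules(b = 4, d = 0.08), system_state(NULL),
                      NULL, horizon = 4000,
                      record_grid = seq(200, 4000, by = 8), seed = 3)
  expect_lt(abs(mean(ts2$qHSC) - 50) / 50, 0.05)
})

test_that("simulation is seed-reproducible and replicates are independent", {
  rules <- birth_death_rules()
  st <- qhsc_state(10)
  a <- simulate_hsc(rules, st, NULL, 100, 0:100, seed = 42)
  b <- simulate_hsc(rules, st, NULL, 100, 0:100, seed = 42)
  expect_identical(a, b)
  c <- simulate_hsc(rules, st, NULL, 100, 0:100, seed = 43)
  expect_false(identical(a$qHSC, c$qHSC))

  # run_replicates: n = 1 is simulate at the base seed; batches reproduce
  r1 <- run_replicates(rules, st, NULL, 50, 0:50, n_replicates = 1,
                       base_seed = 42)
  expect_identical(r1[[1]]$qHSC,
                   simulate_hsc(rules, st, NULL, 50, 0:50, seed = 42)$qHSC)
  batch1 <- run_replicates(rules, st, NULL, 50, 0:50, n_replicates = 4,
                           base_seed = 7)
  batch2 <- run_replicates(rules, st, NULL, 50, 0:50, n_replicates = 4,
                           base_seed = 7)
  expect_identical(batch1, batch2)

  # pure-death across-replicate variance at t ~ 1/(kN): binomial survival
  N <- 200; k <- 0.02; t <- 25
  death <- list(hsc_rule("death", guard = list(cell_state = "qHSC"),
                         effect = list(delete = TRUE),
                         rate_law = list(base_rate = k)))
  reps <- run_replicates(death, qhsc_state(N), NULL, t, c(0, t),
                         n_replicates = 80, base_seed = 100)
  counts <- vapply(reps, function(ts) ts$qHSC[2], numeric(1))
  p_surv <- exp(-k * t)
  expect_lt(abs(mean(counts) - N * p_surv), 3 * sqrt(N * p_surv * (1 - p_surv) / 80))
  v <- var(counts)
  v_exp <- N * p_surv * (1 - p_surv)
  # chi-square-ish band on the sample variance of 80 binomial draws
  expect_gt(v / v_exp, 0.55)
  expect_lt(v / v_exp, 1.7)
})

test_that("perturbations apply exactly at their times, before sampling", {
  st <- system_state(NULL, token_pool(TGFB1_free = 100))
  pr <- list(perturbation(5, c(TGFB1_free = 40)),
             perturbation(10, c(TGFB1_free = 60)))
  # no reactions at all: one dead rule, so amounts are exact
  dead <- list(hsc_rule("dead", guard = list(cell_state = "MFB"),
                        effect = list(delete = TRUE),
                        rate_law = list(base_rate = 1)))
  ts <- simulate_hsc(dead, st, pr, horizon = 12, record_grid = c(0, 5, 10, 12),
                     seed = 1)
  expect_equal(ts$TGFB1_free, c(100, 140, 200, 200))

  # per-cell amounts resolve against the living population at event time
  st2 <- qhsc_state(8)
  ts2 <- simulate_hsc(dead, st2, list(perturbation(2, c(TGFB1_free = 10),
                                                   per_cell = TRUE)),
                      horizon = 4, record_grid = c(0, 2, 4), seed = 1)
  expect_equal(ts2$TGFB1_free, c(0, 80, 80))
})

test_that("configuration errors are rejected", {
  rules <- birth_death_rules()
  st <- qhsc_state(1)
  expect_error(simulate_hsc(rules, st, NULL, 10, record_grid = c(0, 5, 5)),
               "strictly increasing")
  expect_error(simulate_hsc(rules, st, NULL, 10, record_grid = c(0, 20)),
               "within")
  bad_pr <- list(perturbation(5, c(TGFB1_free = 1)),
                 perturbation(5, c(TGFB1_free = 1)))
  expect_error(simulate_hsc(rules, st, bad_pr, 10, 0:10),
               "strictly increasing")
  expect_error(hsc_rule("x", rate_law = list(base_rate = 1),
                        effect = list(tokens = c(ATP = -1))), "unknown token")
  expect_error(hsc_rule("x", rate_law = list(base_rate = 1,
                                             token_factor = "ATP")),
               "token_factor")
})

test_that("model invariants hold along a stimulated trajectory", {
  p <- test_params()
  rules <- build_rules(params = p)
  pr <- kisseleva_protocol(1000, n_stimulations = 4, reversion_months = 1)
  ts <- simulate_hsc(rules, initial_state(p), pr, horizon = 50 * 24,
                     record_grid = seq(0, 50 * 24, by = 12), seed = 9,
                     debug_checks = TRUE)
  # token non-negativity at every sample
  expect_true(all(as.matrix(ts[hsc_token_names()]) >= 0))
  # counts are non-negative integers
  cm <- as.matrix(ts[hsc_cell_states()])
  expect_true(all(cm >= 0) && all(cm == round(cm)))
  # counter pairing in the final microstate
  fc <- attr(ts, "final_counts")
  expect_true(all(fc >= 0))
  # alpha-SMA+ + qHSC + iHSC + apop_sene = total agents at every sample
  expect_equal(ts$alpha_sma + ts$qHSC + ts$iHSC + ts$apop_sene_MFB,
               rowSums(cm))
})
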