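---
title: "Modeling hepatic stellate cell plasticity in fibrosis and reversion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling hepatic stellate cell plasticity in fibrosis and reversion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hscsim)
```

## The biological problem

Liver fibrosis is an excess of extracellular matrix — chiefly type I
collagen (COL1) — deposited by hepatic stellate cells (HSCs). In healthy
liver HSCs are quiescent (qHSC). Injury-driven TGF&beta;1 activates them
(aHSC), and activated cells differentiate over about two weeks into
collagen-secreting myofibroblasts (MFB). When the injury stops, MFBs either
die (apoptosis/senescence) or *inactivate* into a primed state (iHSC) that
is reactivated much faster than a quiescent cell on the next insult
(react_HSC, then react_MFB). How much of the myofibroblast pool takes the
inactivation shortcut — in particular whether *reactivated* myofibroblasts
can be inactivated again — controls whether fibrosis resolves, persists, or
ratchets up across repeated injuries.

`hscsim` is a stochastic simulator of exactly this cell-state network. Each
HSC is an agent with four sites:

* `cell_state` — one of the seven states above;
* `tgfb1_binding` — whether a TGF&beta;1 signal is currently engaged;
* `tgfbr` — receptor at the membrane, internalized, or degraded;
* a bounded counter pair (`intermediate_step`, `control_counter`) whose sum
  is pinned at 14 and which paces the 14-day activation/differentiation
  program one step per day.

Molecules are not agents. Free and bound TGF&beta;1 and the two collagen
pools (high- and low-remodeling) are *tokens*: non-negative continuous
quantities coupled to the agents by hybrid rules. This agent/token split is
what keeps a multiscale cell-and-molecule model tractable: 10^6 ligand
molecules are one number, not 10^6 objects.

## Simulation semantics

The engine is an exact Gillespie direct-method sampler over the rule set. A
rule's propensity is `base_rate x matches x |token| x population`, where
`matches` counts agents satisfying the guard (replaced by the sum of their
counter values for production rules whose output scales with differentiation
progress), `|token|` is an optional token amount (e.g. binding scales with
free TGF&beta;1) and `population` an optional global cell count (collagen
stabilization scales with the number of &alpha;-SMA+ cells). A rule that
would drive any token negative has propensity zero.

Internally agents are stored as counts over the 630 configuration classes
(7 states x 2 binding x 3 receptor x 15 counter values); because agents in a
class are exchangeable this is byte-for-byte equivalent to per-agent
simulation, and per-rule match sums are maintained incrementally. Scheduled
perturbations (TGF&beta;1 stimulations) are applied at exactly their
timestamps, before any sample scheduled at the same instant. Each
`simulate_hsc()` call runs on a private counter-based RNG stream
(splitmix64-seeded xoshiro256++), so a seed fully determines a trajectory
and replicate `i` of a batch uses `base_seed + i - 1` independently of
R's global RNG.

Two reference implementations coexist deliberately: `propensity()`,
`draw_next_event()` and `apply_event()` are plain R and define the
contract; the compiled core is cross-checked against them in the test
suite.

## The three model families

* **reactMFB-wo-inactivation** — react_MFBs can only be eliminated
  (75 rules);
* **reactMFB-with-inactivation** — adds one rule sending a fraction
  (default 5%) of exiting react_MFBs back to the inactivated pool
  (76 rules);
* **iHSC-reversion-to-qHSC** — additionally lets exiting iHSCs revert to
  quiescence (77 rules).

The families are nested: with the react_MFB inactivation fraction set to
zero, family 2 reproduces family 1 event-for-event under the same seed (the
extra rule has zero propensity and consumes no randomness); the test suite
asserts this exactly.

Rule-group decomposition (family 1): quiescent renewal 2; TGF&beta;1 binding
7 (one per cell state, with the apoptotic dead-end state carried at rate 0);
receptor trafficking 3; activation/differentiation 8 (two signal-consuming
state switches, two boundary switches at step 7, four counter-stepping
rules); proliferation 30 (19 basal rules enumerated per counter value —
aHSC steps 3–7, MFB and react_MFB steps 8–14 — plus 11 signal-consuming
rules for aHSC steps 3–7 and react_HSC steps 0–5); collagen 12 (4 basal + 4
signal-boosted production, 2 degradation, stabilization and
destabilization); myofibroblast exit 12 (the 45/55 inactivation/apoptosis
split for MFBs, react_MFB apoptosis, per-counter clearance of
apoptotic/senescent cells, slow iHSC elimination); free-TGF&beta;1
clearance 1. The per-counter enumeration mirrors the Kappa-style encoding, where
a daughter cell's counter must be written explicitly; react_HSC
proliferation is signal-driven only, consistent with reactivation itself
being TGF&beta;1-dependent.

Two structural conventions worth calling out:

* **Counter scheme.** The activated phase steps through counters 0–6 (seven
  firings), the state switch fires at counter 7, and the myofibroblast
  phase steps through 7–13, completing at 14. Inactivation resets the pair
  to (0, 14) in one atomic effect. Quiescent cells only exist at step 0 and
  the compiler rejects any rule effect that would violate this or the
  sum-to-14 pairing.
* **Exit semantics.** "Absence of TGF&beta;1" is read per cell: only agents
  whose own binding site is free can exit. The fate split (45/55 for MFBs,
  5/95 for react_MFBs by default) is implemented as two competing rules
  whose rates are `frac x k_exit` and `(1 - frac) x k_exit`, so fate
  proportions equal the fractions while the overall exit half-life is
  preserved.

## Parameters

Every duration is stored in hours. Durations of exponential
elimination processes (cell death, exits, ligand clearance, signal
initiation) are half-lives, converted as `rate = log(2)/t_half`
(`halflife_mode = "reciprocal"` switches to `1/t`). Paced durations — the
24-hour counter step, the 30-minute receptor trafficking time, the boundary
dwell — are mean sojourn times (`1/t`): fourteen daily steps then take 14
days in expectation, which the timing test pins to &plusmn;20%.

Quantities fixed by published measurements: the 14-step/14-day program with
the quiescent-to-activated switch at day 7; twice-as-fast proliferation of
aHSCs relative to MFBs; 45% of exiting MFBs inactivating; a 3.5-fold faster
signal initiation for inactivated cells; myofibroblast basal collagen
output 10x the activated-cell output, with bound-signal boosts of 10x
(aHSC/react_HSC) and 2x (MFB/react_MFB); 30-minute receptor trafficking
with a high recycling fraction.

The remaining rates (binding, clearance, proliferation, exit, collagen
turnover, quiescent renewal, iHSC elimination) have no directly reported
values; they were fixed once by the package's own block calibration
(`block_calibrate()`, mirroring the study's block-based estimation:
collagen-producing cells first, then react_MFB inactivation, then the
iHSC/qHSC balance, then collagen turnover) against the published
benchmark under chronic twice-weekly stimulation: collagen x12 at one
month and x14 at two months, a 1.43-fold rise in &alpha;-SMA+ cells at two
months, a 50/50 iHSC/qHSC split after one month of recovery, return to the
initial cell count at six months, and a ~98% first-stimulation activation
with ~2% of quiescent cells persisting. These values are the package
defaults and carry provenance tags
(`attr(default_parameters(), "provenance")`).

Dose bookkeeping: a stimulation dose is "molecules per cell", resolved at
event time against the living population (every state except
apop_sene_MFB); `dose_basis = "initial"` resolves against the initial count
instead. Token quanta are one unit per event for every agent-coupled move;
the one exception is bulk clearance of free TGF&beta;1, which removes 100
units per event at propensity `(k/100)|T|` — the first-order mean is
unchanged and the relative fluctuation this adds is of order 10^-2 at the
10^6-token scale, while keeping event counts tractable.

## What the simulations do and do not show

The simulator reproduces the discriminating behavior at the heart of the
model comparison: without react_MFB inactivation the activated pool peaks
and then declines while stimulation is still running; with inactivation it
is sustained, and the week-8 collagen response grows monotonically in the
inactivation fraction, steeply at 50%. The quantitative spread between the
frozen variant predictions is narrower in our calibration than the
published one (our family-1 and 5% trajectories sit closer together); those
per-variant fold-changes were *not* used as calibration targets and the
acceptance suite reports them as measured, pass or fail.

Two published behaviors are in tension in this reconstruction and we chose
sides deliberately. With binding kinetics fast enough to saturate the
receptors at 10,000 molecules/cell and ligand clearance fast enough that
the excess at 100,000 molecules/cell disappears before it can re-bind, the
dose–response curves superpose — but bound-signal consumption then budgets
the divisions of reactivated cells so tightly that the inactivation-loop
effect becomes statistically invisible. With the default (slower) binding
kinetics the loop effect is strong and monotone, but the inter-stimulation
re-binding window grows with the logarithm of the dose, so the
100,000-molecules/cell trajectories overshoot the 10,000 ones instead of
superposing, and inactivated cells carried across relapse cycles are
consumed by reactivation (whose myofibroblast progeny are 95% eliminated)
rather than accumulating. We kept the loop effect, the model's central
claim; the saturation and relapse-accumulation checks in the acceptance
suite document the cost and are expected to fail at the defaults.

Calibration was performed at 100 initial quiescent cells. Fold-change
observables are scale-free in expectation, but replicate noise scales as
1/sqrt(N); the printed replicate SDs in the source figures are
substantially tighter than a 100-cell population produces, so tolerance
checks in the tests operate on replicate means of 10 runs, the same
aggregation the figures use.

Known limitations, deliberate:

* No intracellular signaling (Smads), immune compartment, or MMP/TIMP
  detail — matrix remodeling is collapsed into the two collagen tokens.
* No spatial structure; "per cell" doses are global mean-field quantities.
* Free TGF&beta;1 clearance between stimulations is a single first-order
  rate; its half-life (12 h by calibration) stands in for the whole
  injury-resolution cascade.
* The healthy-liver collagen baseline has no producing cells, so it decays
  on the slow low-remodeling time scale rather than being held at steady
  state; over the eight-month benchmark this drift is small compared to the
  14-fold injury signal.

## Problem sizes in the test and acceptance suites

Unit and property tests run on small fixtures (tens of agents, minutes of
simulated time) plus closed-form oracles for the exponential waiting time,
birth-death stationary mean, linear token decay and binomial rule choice.
The acceptance suite runs the full benchmark at the study conditions
(N = 100 cells, 16 stimulations, 10 replicates, eight-month horizon, ~10^6
events per replicate) — a few seconds per replicate in the compiled
engine — and the dose-saturation, relapse-accumulation and
reversion-insensitivity properties at 5–10 replicates with rank tests at
alpha = 0.01.

## Reproducing a benchmark run

```{r, eval = FALSE}
p <- default_parameters("reactMFB-with-inactivation")
rules <- build_rules(params = p)
protocol <- kisseleva_protocol(dose = 10000)
reps <- run_replicates(rules, initial_state(p), protocol,
                       horizon = protocol$horizon,
                       record_grid = seq(0, protocol$horizon, by = 24),
                       n_replicates = 10, base_seed = 1)
agg <- aggregate_replicates(reps)
fold_change(reps[[1]], "col1_total", t = 60 * 24)   # week-8 collagen fold
```
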