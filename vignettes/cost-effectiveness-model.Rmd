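---
title: "A semi-Markov cure model for trial-based cost-effectiveness analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A semi-Markov cure model for trial-based cost-effectiveness analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(curecea)
library(dplyr)
```

## The decision problem

Adding rituximab to LMB chemotherapy reduces events and deaths in children
and adolescents with high-risk mature B-cell non-Hodgkin lymphoma, but the
drug adds cost. `curecea` implements the decision-analytic model used to
weigh that trade-off from a payer perspective: a four-state semi-Markov
cohort model with monthly cycles, fed by Kaplan–Meier estimates from
patient-level trial data, with costs and (quality-adjusted) life-years
accumulated under discounting, and uncertainty propagated by probabilistic
and deterministic sensitivity analysis.

Because the underlying trial data are confidential, the package ships a
synthetic patient-level generator with the same statistical structure, so
the whole pipeline is runnable and testable end to end.

## Model structure

Four mutually exclusive health states: **Event-free**, **Event/Post-event**,
**Cured** and **Death** (from any cause). Cured and Death are absorbing.
Events comprise primary refractory disease, relapse, progression and second
cancer. Two structural assumptions, both supported by the clinical course
of this disease, drive the state logic:

* every first event occurs within 18 months of diagnosis, and
* a patient who spends 18 months event-free — from diagnosis or from a
  first event — is cured.

Event/Post-event is therefore a *tunnel state*: its exit probabilities
depend on the time since entry (the "tunnel age"), and after 18 months in
the tunnel the survivor exits to Cured with probability 1. Likewise an
Event-free patient reaching month 18 moves to Cured with probability 1.
After cycle 36 no occupancy remains outside the absorbing states, whatever
the horizon. No general-population background mortality is applied — these
are pediatric patients whose baseline mortality over a 3–10-year horizon is
negligible next to disease-related risk.

## From survival curves to cycle probabilities

Transition probabilities are time-varying, derived from Kaplan–Meier
curves (`km_curve()`, a tidy wrapper over `survival::survfit()` keeping
Greenwood standard errors). For a cycle of length $u$ = 1 month ending at
$t$, the conditional probability of the transition is

$$p(t) = 1 - \frac{S(t)}{S(t-u)},$$

implemented in `cycle_probability()`. Compounding these probabilities
reconstructs the KM curve exactly at its step points — a chain identity the
test suite asserts to 1e-12.

Three transitions are estimated (`build_schedule()`):

* **Event-free → Event/Post-event**: KM of time to first event, censoring
  death, in the control arm. The intervention arm applies the trial-level
  event-free-survival hazard ratio on the survival scale,
  $p_{int} = 1 - (1-p_{ctl})^{HR}$ (`apply_hazard_ratio()`), with
  $HR = 0.317$ at the point estimate.
* **Event-free → Death**: KM of death censoring events, per arm (pooled
  across arms in a named sensitivity analysis).
* **Event/Post-event → Death**: KM of post-event survival measured from
  event onset, indexed by tunnel age; pooled across arms in the base case
  because events are few (estimated per arm in a sensitivity analysis).

Ties between events and censorings at the same time follow the standard KM
convention: events first.

### Numerical and structural choices

Several details are underdetermined by the model description alone; the
package pins them explicitly and uses them identically everywhere:

* **Within-cycle ordering.** Death and the event compete inside a cycle.
  Death is applied first, then the event among survivors:
  $P(\text{event}) = (1-p_{death})\,p_{event}$. Because each probability
  is estimated censoring the other, this competing-decrement ordering
  keeps each marginal no larger than its KM input.
* **Cure timing.** The cure transition applies after the 18th cycle's
  death/event draws, to its survivors: the whole 18th month is at risk.
* **Tunnel clock.** Tunnel age 0 is the cycle of event entry; the
  age-0 death probability applies in the following cycle (a patient
  cannot enter and exit the tunnel within one month).
* **No half-cycle correction.** State membership for accrual is the state
  occupied during the month (the cycle-start occupancy), discounted at the
  cycle's end index; trace snapshots record cycle-end occupancy.
* **Exhausted risk sets.** A cycle with nobody at risk keeps a fixed zero
  probability and carries no sampled uncertainty.

The cohort engine (`run_cohort()`) is validated against an
individual-level microsimulation (`microsim_cohort()`) implementing the
same precedence rules patient by patient; on random schedules with 200,000
simulated patients the maximum occupancy gap stays below 0.005.

## Economics

Accumulation (`accumulate_outcomes()`) values each month at the occupied
state with geometric monthly discounting,
$(1+r)^{-t/12}$ with $r$ = 2.5%/year (range 0–5%). Defaults are 2020 euros:

| Parameter | Value | PSA distribution |
|---|---|---|
| Monthly Event-free cost, control | €3,238 | gamma(198.06, 0.06116) |
| Monthly Event-free cost, intervention (excl. rituximab) | €2,864 | gamma(83.83, 0.02927) |
| Rituximab per patient | €4,108 | gamma(7421.9, 1.81) |
| Monthly Event/Post-event cost | €5,276 | gamma(7.65, 0.001451) |
| Immunoglobulin one-time, control entry | €311 (€3,924 × 8%) | gamma on per-user cost |
| Immunoglobulin one-time, intervention entry | €388 (€2,545 × 15%) | gamma on per-user cost |
| Immunoglobulin one-time, Cured entry | €412 (€15,020 × 3%) | gamma on per-user cost |
| Utilities EF / PE / Cured | 0.8 / 0.4 / 0.9 | beta, SE = 20% of mean |
| EFS hazard ratio | 0.317 | log-normal(−1.14938, 0.38759) |

Every gamma's mean (shape/rate) reproduces its point value to within the
rounding of the printed shape parameters (the largest gap, for rituximab,
is 0.18%). The one-time immunoglobulin entries use the stated expected
values rather than the rate × mean products, which differ by rounding in
the last digit (0.08 × 3,924 = €313.9 vs €311); the registry keeps the
stated point values and draws the per-user cost in the PSA.

Two cost-timing conventions matter and are fixed:

* the rituximab per-patient total is spread uniformly over the first six
  event-free cycles (the six administrations), weighted by remaining
  event-free occupancy — the alternative of charging it at entry changes
  discounted results by well under 0.5%, but a convention must be chosen;
* the Cured-entry immunoglobulin cost applies to every entrant into Cured
  at the entry cycle, which is why a 10-year horizon leaves total
  undiscounted costs unchanged (no cost-bearing occupancy survives cycle
  36) while life-years keep accruing.

`compare_arms()` computes incremental effect and cost, classifies
dominance, and evaluates the incremental net monetary benefit
$INMB(\lambda) = \lambda\,\Delta E - \Delta C$; the ICER
$\Delta C / \Delta E$ is reported only when neither strategy dominates.
Life-years are the base-case outcome; QALYs are an exploratory variant
(`analysis = "qaly"`), with utilities taken from adult NHL assessments and
therefore deliberately varied over wide intervals.

## Uncertainty

The PSA (`run_psa()`, 10,000 draws for a full analysis) samples every
uncertain parameter independently: one log-normal hazard-ratio draw per
simulation applied to all cycles, gammas for costs, betas for utilities
(method-of-moments; feasibility of the SE is checked at run time and
clamped with a warning if violated, which the default registry never
triggers), and per-cycle independent betas for each estimated transition
probability. The beta shapes use the cycle's KM risk set with a Jeffreys
½ adjustment, $(d_k + \tfrac12,\; n_k - d_k + \tfrac12)$, so zero-event
cycles still carry uncertainty — standard practice for KM-derived
probabilities, since the published model states the family but not the
shapes. Whether to perturb whole curves instead of cycles, or to correlate
cycles, is equally unstated; independent per-cycle draws are the simplest
reproducible choice, and the chain identity plus CEAC reconstruction
tests make the consequences auditable. Draws that fail to evaluate are
dropped and counted, never silently resampled, so the effective
denominator is reproducible.

The CEAC reports $P(INMB(\lambda) > 0)$ over a €0–100,000 grid in €1,000
steps (reference threshold €50,000); it is recomputable from the persisted
draw table by construction. The tornado (`tornado()`) re-runs the
deterministic model at each parameter's range bounds — hazard ratio at its
95% CI, rituximab at ±30%, discounting at 0–5%, state costs and
immunoglobulin costs at their 95% CIs, utilities at their CIs in the QALY
variant — holding everything else at base case, and sorts bars by width.

## The synthetic trial generator

`simulate_trial()` emulates the statistical structure the analysis
assumes, not any real patient. Control-arm event-free survival is a
mixture cure law
$$S_{ctl}(t) = \pi + (1-\pi)\,S_T(t),$$
with $S_T$ an exponential truncated to (0, 18] months — the simplest law
that makes a cured majority coexist with the all-events-by-18-months
constraint. The intervention arm draws from
$S_{int}(t) = S_{ctl}(t)^{HR}$, i.e. proportional hazards hold exactly on
the marginal scale, which is what makes hazard-ratio recovery from the
generated data a well-posed check. Defaults pin the study conditions: 164
patients per arm, $HR = 0.317$, $\pi = 0.82$ (a control 3-year
event-free survival of ~82%, consistent with 28 control-arm events among
164), an event hazard of 0.20/month among the non-cured (events
concentrated in the first year), event-free death at 0.0015/month (rare in
this population), post-event death at 0.045/month (~42% survival 18
months after an event, realistic for relapsed/refractory mature B-NHL),
administrative censoring at 36 months, and a 69-patient hospitalization
cost subgroup. `simulate_cost_records()` adds gamma-noised monthly costs
labelled by the attribution rule — event-free months end 7 days
(7/30.4375 months) before an event, post-event months run at most 18
months from it — so the costing stage can re-derive unbiased per-state
means from the records.

What the generator does **not** emulate: covariate structure (histology,
stage, country), non-proportional hazards, uniform-accrual censoring,
toxicity-specific hospitalization patterns, or correlated cost-survival
trajectories. Passing tests therefore demonstrate correctness of the
estimation and modelling machinery under the stated assumptions, not
fidelity of any particular parametric law to the real trial.

## Problem sizes

Test and example runs use sizes chosen to make Monte Carlo error
negligible relative to each assertion's tolerance: 328 patients for
pipeline runs (the trial's size), 4,000–10,000 patients for parameter
recovery and convergence checks, 200,000 patients for the
cohort-vs-microsimulation oracle (binomial error < 0.005), and PSA sizes
from dozens (schema and determinism checks) to 10,000 (full analyses).

## Known limitations

* The generator's event-time law is a stand-in; only parameter recovery,
  not distributional fidelity, is claimed.
* PSA draws are independent across parameters and cycles; any real-world
  correlation (e.g. between arm-specific costs) is not represented.
* The rituximab cost spread and the printed-value convention for one-time
  immunoglobulin costs are conventions, not estimates; both are
  deliberately exposed as parameters.
* Costs reflect a single payer perspective (hospital costs, 2020 euros);
  no societal costs or re-costing to other systems.

## A worked run

```{r, eval = FALSE}
trial <- simulate_trial(trial_config(seed = 1)) |>
  simulate_cost_records()

res <- run_cea(trial, model_params(), analysis = "base_ly",
               n_sims = 10000, seed = 2, run_tornado = TRUE)
tidy(res)
autoplot(res$psa)         # acceptability curve
plot_ce_plane(res$psa)    # incremental scatter
autoplot(res$tornado)     # one-way sensitivity
write_cea_outputs(res, "results/base_ly")
```
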