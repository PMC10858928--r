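#' Model parameter registry
#'
#' The full parameter set of the cost-effectiveness model: point values,
#' probabilistic-sensitivity-analysis distributions, and deterministic
#' one-way sensitivity ranges. Defaults are the French 2020-euro values
#' used in the trial-based evaluation: an event-free-survival hazard ratio
#' of 0.317 (log-normal mu -1.14938, sigma 0.38759 on the log scale,
#' 95% CI 0.148-0.677), state utilities 0.8 / 0.4 / 0.9 (event-free /
#' post-event / cured; SE 20% of the mean, beta-distributed), monthly
#' event-free hospital costs of 3238 (control) and 2864 euros
#' (intervention, excluding rituximab), a 4108-euro per-patient rituximab
#' cost, a 5276-euro monthly post-event cost, one-time immunoglobulin
#' costs of 311 / 388 euros at model entry (control / intervention: per-user
#' means 3924 and 2545 euros at use rates 8% and 15%) and 412 euros on entry
#' into Cured (15,020 euros at 3%), and 2.5% annual discounting. Costs are
#' gamma-distributed in the PSA with the shape/rate pairs recorded in
#' `$psa`; each gamma's mean `shape/rate` reproduces its point value.
#'
#' @param hr Event-free-survival hazard ratio (intervention vs control).
#' @param utilities Named vector `event_free`, `post_event`, `cured`,
#'   `dead`.
#' @param monthly_cost_ef_control,monthly_cost_ef_intervention Monthly
#'   event-free hospital cost per arm, euros (intervention excludes the
#'   rituximab drug cost).
#' @param rituximab_cost Per-patient rituximab cost, euros, spread over the
#'   first `ritux_spread_cycles` event-free cycles.
#' @param monthly_cost_pe Monthly Event/Post-event cost, euros.
#' @param ig_onetime One-time immunoglobulin costs, euros: named vector
#'   `ef_control`, `ef_intervention` (applied at model entry) and `cured`
#'   (applied on entry into Cured).
#' @param discount_annual Annual discount rate for costs and outcomes.
#' @param horizon_years Model horizon, years (3 base case; 10 sensitivity).
#' @param wtp Reference willingness-to-pay, euros per LY (or QALY).
#' @param wtp_grid Willingness-to-pay grid for the acceptability curve.
#' @param ritux_spread_cycles Cycles over which the rituximab cost accrues.
#' @param utility_se_frac PSA standard error of each utility as a fraction
#'   of its mean.
#' @return An object of class `model_params`: the point values above plus
#'   `$psa` (distribution specs) and `$dsa` (one-way ranges).
#' @examples
#' pars <- model_params()
#' pars$hr
#' pars$psa$gamma["monthly_cost_ef_control", ]
#' @export
model_params <- function(hr = 0.317,
                         utilities = c(event_free = 0.8, post_event = 0.4,
                                       cured = 0.9, dead = 0),
                         monthly_cost_ef_control = 3238,
                         monthly_cost_ef_intervention = 2864,
                         rituximab_cost = 4108,
                         monthly_cost_pe = 5276,
                         ig_onetime = c(ef_control = 311,
                                        ef_intervention = 388, cured = 412),
                         discount_annual = 0.025,
                         horizon_years = 3,
                         wtp = 50000,
                         wtp_grid = seq(0, 100000, by = 1000),
                         ritux_spread_cycles = 6L,
                         utility_se_frac = 0.2) {
  stopifnot(hr > 0, all(utilities >= 0 & utilities <= 1),
            monthly_cost_ef_control >= 0, monthly_cost_ef_intervention >= 0,
            rituximab_cost >= 0, monthly_cost_pe >= 0, all(ig_onetime >= 0),
            discount_annual >= 0, discount_annual <= 0.05,
            horizon_years > 0)

  gamma_specs <- rbind(
    monthly_cost_ef_control      = c(198.06, 0.06116),
    monthly_cost_ef_intervention = c(83.83,  0.02927),
    rituximab_cost               = c(7421.9, 1.81),
    monthly_cost_pe              = c(7.65,   0.001451),
    ig_user_cost_ef_control      = c(9.53,   0.002429),
    ig_user_cost_ef_intervention = c(23.48,  0.009227),
    ig_user_cost_cured           = c(7.21,   0.0004799)
  )
  colnames(gamma_specs) <- c("shape", "rate")

  psa <- list(
    hr_lnorm = c(meanlog = -1.14938, sdlog = 0.38759),
    gamma = gamma_specs,
    ig_rates = c(ef_control = 0.08, ef_intervention = 0.15, cured = 0.03),
    utility_se_frac = utility_se_frac
  )

  dsa <- list(
    hr = c(0.148, 0.677),
    discount_annual = c(0, 0.05),
    rituximab_cost = c(2876, 5340),
    monthly_cost_ef_control = c(2793, 3685),
    monthly_cost_ef_intervention = c(2298, 3533),
    monthly_cost_pe = c(1870, 9015),
    ig_onetime_ef_control = c(163, 539),
    ig_onetime_ef_intervention = c(243, 549),
    ig_onetime_cured = c(146, 735),
    utility_event_free = c(0.41, 0.99),
    utility_post_event = c(0.25, 0.56),
    utility_cured = c(0.33, 1.00)
  )

  structure(
    list(hr = hr, utilities = utilities,
         monthly_cost_ef_control = monthly_cost_ef_control,
         monthly_cost_ef_intervention = monthly_cost_ef_intervention,
         rituximab_cost = rituximab_cost,
         monthly_cost_pe = monthly_cost_pe,
         ig_onetime = ig_onetime,
         discount_annual = discount_annual,
         horizon_years = horizon_years,
         wtp = wtp, wtp_grid = wtp_grid,
         ritux_spread_cycles = as.integer(ritux_spread_cycles),
         psa = psa, dsa = dsa),
    class = "model_params"
  )
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n")
  cat(sprintf("  HR %.3f | discount %.1f%%/yr | horizon %g yr | WTP %s\n",
              x$hr, 100 * x$discount_annual, x$horizon_years,
              format(x$wtp, big.mark = ",")))
  cat(sprintf("  EF cost/mo: %0.f (ctl) / %0.f (int) + rituximab %0.f;",
              x$monthly_cost_ef_control, x$monthly_cost_ef_intervention,
              x$rituximab_cost),
      sprintf("PE cost/mo: %0.f\n", x$monthly_cost_pe))
  invisible(x)
}

#' Monthly discount factor from an annual rate
#'
#' Geometric sub-annual compounding: `(1 + rate)^(-cycle / 12)`, so twelve
#' monthly factors compose to exactly one annual factor.
#'
#' @param cycle Cycle index (months from model start), >= 0.
#' @param annual_rate Annual discount rate, >= 0.
#' @return The discount factor(s).
#' @examples
#' discount_factor(12, 0.025)  # one year: 1 / 1.025
#' @export
discount_factor <- function(cycle, annual_rate) {
  stopifnot(all(cycle >= 0))
  if (any(annual_rate < 0)) abort("Negative discount rates are not allowed.")
  (1 + annual_rate)^(-cycle / 12)
}

#' Accumulate discounted life-years, QALYs and costs over a trace
#'
#' Values each model month at the state occupied during it (the occupancy
#' at the start of the cycle), discounted with [discount_factor()] at the
#' cycle's end index. Life-years count event-free, post-event and cured
#' occupancy; QALYs weight the same person-time by state utilities. Costs
#' accrue monthly in Event-free (per-arm hospital cost, plus the rituximab
#' per-patient total spread over the first `ritux_spread_cycles` cycles of
#' the intervention arm, weighted by remaining event-free occupancy) and
#' in Event/Post-event (tunnel ages below 18 months only), plus one-time
#' immunoglobulin costs: the arm's expected cost at model entry and the
#' cured-state expected cost for each entrant into Cured at the entry
#' cycle. Cured and Dead bear no per-cycle cost; Dead accrues no utility.
#'
#' @param trace A `cohort_trace` from [run_cohort()].
#' @param params A [model_params()].
#' @param arm `"control"` or `"intervention"`; defaults to the trace's arm.
#' @return A one-row tibble of class `arm_outcome`: `arm`, `ly`, `qaly`,
#'   `cost` (all discounted, per patient).
#' @examples
#' trial <- simulate_trial(trial_config(n_per_arm = 100, seed = 3))
#' sched <- build_schedule(trial, model_params())
#' accumulate_outcomes(run_cohort(sched, "control"), model_params())
#' @export
accumulate_outcomes <- function(trace, params, arm = attr(trace, "arm")) {
  H <- attr(trace, "horizon_cycles")
  if (H != round(params$horizon_years * 12)) {
    abort(sprintf(
      "Trace horizon (%d cycles) does not match params horizon (%g years).",
      H, params$horizon_years))
  }
  occ <- start_of_cycle_occupancy(trace)
  res <- accumulate_from_occ(occ, params, arm)
  out <- tibble(arm = arm, ly = res$ly, qaly = res$qaly, cost = res$cost)
  class(out) <- c("arm_outcome", class(out))
  out
}

# shared accumulation arithmetic over start-of-cycle occupancy vectors
accumulate_from_occ <- function(occ, params, arm) {
  H <- length(occ$ef)
  disc <- discount_factor(seq_len(H), params$discount_annual)
  u <- params$utilities

  alive <- occ$ef + occ$pe + occ$cured
  ly <- sum(alive * disc) / 12
  qaly <- sum((occ$ef * u[["event_free"]] + occ$pe * u[["post_event"]] +
                 occ$cured * u[["cured"]]) * disc) / 12

  ef_monthly <- if (arm == "control") params$monthly_cost_ef_control
                else params$monthly_cost_ef_intervention
  cost <- sum(occ$ef * ef_monthly * disc) +
    sum(occ$pe * params$monthly_cost_pe * disc) +
    params$ig_onetime[[paste0("ef_", arm)]] +
    sum(occ$cured_entrants * params$ig_onetime[["cured"]] * disc)
  if (arm == "intervention") {
    sp <- seq_len(params$ritux_spread_cycles)
    cost <- cost + sum(occ$ef[sp] * disc[sp]) *
      params$rituximab_cost / params$ritux_spread_cycles
  }
  list(ly = ly, qaly = qaly, cost = cost)
}

#' Compare two arm outcomes
#'
#' Computes incremental effects and costs (intervention minus control),
#' classifies dominance, and evaluates the incremental net monetary
#' benefit `INMB = wtp * delta_e - delta_c` at the reference
#' willingness-to-pay. The ICER `delta_c / delta_e` is reported only in
#' the trade-off case (neither strategy dominant).
#'
#' @param control,intervention `arm_outcome` rows from
#'   [accumulate_outcomes()].
#' @param wtp Willingness-to-pay, euros per unit of effect.
#' @param effect `"ly"` or `"qaly"`: which effect measure drives the
#'   incremental analysis.
#' @return A list of class `cea_result`: `delta_e`, `delta_ly`,
#'   `delta_qaly`, `delta_c`, `dominance` (`"intervention dominant"`,
#'   `"comparator dominant"` or `"trade-off"`), `icer`, `inmb`, `wtp`,
#'   `effect`, and the two arm outcomes.
#' @examples
#' ctl <- tibble::tibble(arm = "control", ly = 2.64, qaly = 2.17,
#'                       cost = 63190)
#' int <- tibble::tibble(arm = "intervention", ly = 2.77, qaly = 2.32,
#'                       cost = 59480)
#' compare_arms(ctl, int, wtp = 50000)
#' @export
compare_arms <- function(control, intervention, wtp = 50000,
                         effect = c("ly", "qaly")) {
  effect <- match.arg(effect)
  delta_ly <- intervention$ly - control$ly
  delta_qaly <- intervention$qaly - control$qaly
  delta_c <- intervention$cost - control$cost
  delta_e <- if (effect == "ly") delta_ly else delta_qaly

  dominance <- if (delta_e > 0 && delta_c < 0) "intervention dominant"
    else if (delta_e < 0 && delta_c > 0) "comparator dominant"
    else "trade-off"
  icer <- if (dominance == "trade-off" && delta_e != 0) delta_c / delta_e
    else NA_real_

  structure(
    list(delta_e = delta_e, delta_ly = delta_ly, delta_qaly = delta_qaly,
         delta_c = delta_c, dominance = dominance, icer = icer,
         inmb = wtp * delta_e - delta_c, wtp = wtp, effect = effect,
         control = control, intervention = intervention),
    class = "cea_result"
  )
}

#' Incremental net monetary benefit at arbitrary willingness-to-pay
#'
#' @param result A `cea_result`.
#' @param wtp Willingness-to-pay value(s), euros per effect unit.
#' @return `wtp * delta_e - delta_c`, vectorized over `wtp`.
#' @export
inmb_at <- function(result, wtp) {
  wtp * result$delta_e - result$delta_c
}

#' @export
print.cea_result <- function(x, ...) {
  cat(sprintf("<cea_result> (%s)\n", x$effect))
  cat(sprintf("  dE = %.4f %s | dC = %.0f EUR | %s\n",
              x$delta_e, toupper(x$effect), x$delta_c, x$dominance))
  cat(sprintf("  INMB at %s EUR/%s: %.0f EUR\n",
              format(x$wtp, big.mark = ","), toupper(x$effect), x$inmb))
  invisible(x)
}

#' Re-derive per-state monthly hospital cost means from trial cost records
#'
#' Inverts the state-attribution rule of the synthetic cost generator:
#' averages the recorded monthly amounts by attributed state (and arm for
#' the event-free state, where treatment differs between arms).
#'
#' @param trial A `trial_data` with cost records
#'   ([simulate_cost_records()]).
#' @param pool_ef Combine both arms when estimating the event-free monthly
#'   cost (the pooled-cost sensitivity analysis).
#' @return A tibble `state`, `arm`, `mean_monthly_cost`, `n_records`.
#' @export
estimate_state_costs <- function(trial, pool_ef = FALSE) {
  costs <- trial$costs
  if (nrow(costs) == 0) abort("No cost records: run simulate_cost_records().")
  costs <- left_join(costs,
                     select(trial$patients, patient_id = "id", "arm"),
                     by = "patient_id")
  ef <- filter(costs, .data$state == "event_free")
  ef_tbl <- if (pool_ef) {
    summarise(ef, state = "event_free", arm = "pooled",
              mean_monthly_cost = mean(.data$amount_eur),
              n_records = dplyr::n())
  } else {
    ef |>
      group_by(.data$arm) |>
      summarise(mean_monthly_cost = mean(.data$amount_eur),
                n_records = dplyr::n(), .groups = "drop") |>
      mutate(state = "event_free") |>
      select("state", "arm", "mean_monthly_cost", "n_records")
  }
  pe <- filter(costs, .data$state == "post_event")
  pe_tbl <- summarise(pe, state = "post_event", arm = "pooled",
                      mean_monthly_cost = mean(.data$amount_eur),
                      n_records = dplyr::n())
  bind_rows(ef_tbl, pe_tbl)
}
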