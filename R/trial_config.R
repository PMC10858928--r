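#' Configuration for the synthetic two-arm trial generator
#'
#' Bundles every knob of the synthetic patient-level trial: arm sizes, the
#' event-time law (a mixture-cure model whose non-cured component is an
#' exponential truncated to the first 18 months), death hazards, censoring,
#' and the cost-generating process for the hospitalization-cost subgroup.
#'
#' The defaults emulate a pediatric high-risk mature B-NHL trial randomizing
#' 164 patients per arm between LMB chemotherapy and LMB plus rituximab:
#' a cured majority (control 3-year event-free survival around 82%), an
#' event-free survival hazard ratio of 0.317 in favour of the intervention,
#' all first events within 18 months of diagnosis, administrative censoring
#' at 36 months, and a 69-patient subgroup with per-month hospitalization
#' cost records.
#'
#' @param n_per_arm Patients per arm.
#' @param hr_event True event-free-survival hazard ratio
#'   (intervention vs control) applied on the marginal event hazard.
#' @param cure_fraction_control Probability that a control patient never
#'   experiences an event.
#' @param event_rate_control Monthly event hazard among non-cured control
#'   patients (before truncation to 18 months).
#' @param death_after_event_rate Monthly death hazard from event onset.
#' @param death_event_free_rate Monthly hazard of event-free death.
#' @param admin_censor_months Administrative censoring time, months.
#' @param cost_subgroup_size Number of patients (across arms) with
#'   hospitalization cost records.
#' @param cost_params Named list of per-state monthly cost generators, each
#'   `list(mean = , shape = )` for a gamma draw; names `ef_control`,
#'   `ef_intervention`, `post_event`.
#' @param ig_rates Named list: immunoglobulin-use probabilities `ef_control`,
#'   `ef_intervention`, `cured`, and per-user mean costs
#'   `mean_ef_control`, `mean_ef_intervention`, `mean_cured` (euros).
#' @param rituximab_mg_mean,rituximab_mg_shape Gamma parameters for total
#'   rituximab dose (mg) per intervention-arm patient (six administrations;
#'   about 2853 mg at 1.44 euro/mg gives the 4108 euro mean drug cost).
#' @param seed Integer seed; the generator is deterministic given the seed.
#'
#' @return An object of class `trial_config` (a validated named list).
#' @examples
#' cfg <- trial_config(n_per_arm = 20, seed = 1)
#' cfg$hr_event
#' @export
trial_config <- function(n_per_arm = 164L,
                         hr_event = 0.317,
                         cure_fraction_control = 0.82,
                         event_rate_control = 0.20,
                         death_after_event_rate = 0.045,
                         death_event_free_rate = 0.0015,
                         admin_censor_months = 36,
                         cost_subgroup_size = 69L,
                         cost_params = list(
                           ef_control = list(mean = 3238, shape = 2),
                           ef_intervention = list(mean = 2864, shape = 2),
                           post_event = list(mean = 5276, shape = 2)
                         ),
                         ig_rates = list(
                           ef_control = 0.08, ef_intervention = 0.15,
                           cured = 0.03,
                           mean_ef_control = 3924, mean_ef_intervention = 2545,
                           mean_cured = 15020
                         ),
                         rituximab_mg_mean = 4108 / 1.44,
                         rituximab_mg_shape = 50,
                         seed = 1L) {
  if (!is.numeric(n_per_arm) || n_per_arm < 1) {
    abort("`n_per_arm` must be a positive count.")
  }
  stopifnot(hr_event > 0,
            cure_fraction_control >= 0, cure_fraction_control <= 1,
            event_rate_control >= 0,
            death_after_event_rate >= 0, death_event_free_rate >= 0,
            admin_censor_months > 0)
  if (cost_subgroup_size > 2 * n_per_arm) {
    abort("`cost_subgroup_size` cannot exceed the total number of patients.")
  }
  rates <- unlist(ig_rates[c("ef_control", "ef_intervention", "cured")])
  stopifnot(all(rates >= 0 & rates <= 1))
  if (event_rate_control > 0 && event_rate_control * CURE_MONTHS < 0.01) {
    warn(paste("`event_rate_control` is so small that truncation of event",
               "times to 18 months is nearly vacuous."))
  }
  structure(
    list(n_per_arm = as.integer(n_per_arm), hr_event = hr_event,
         cure_fraction_control = cure_fraction_control,
         event_rate_control = event_rate_control,
         death_after_event_rate = death_after_event_rate,
         death_event_free_rate = death_event_free_rate,
         admin_censor_months = admin_censor_months,
         cost_subgroup_size = as.integer(cost_subgroup_size),
         cost_params = cost_params, ig_rates = ig_rates,
         rituximab_mg_mean = rituximab_mg_mean,
         rituximab_mg_shape = rituximab_mg_shape,
         seed = as.integer(seed)),
    class = "trial_config"
  )
}

#' @export
print.trial_config <- function(x, ...) {
  cat("<trial_config>\n")
  cat(sprintf("  %d patients/arm, EFS HR %.3f, control cure fraction %.2f\n",
              x$n_per_arm, x$hr_event, x$cure_fraction_control))
  cat(sprintf("  censoring at %.0f months; cost subgroup n = %d; seed %d\n",
              x$admin_censor_months, x$cost_subgroup_size, x$seed))
  invisible(x)
}
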