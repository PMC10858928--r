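#' Deterministic one-way (tornado) sensitivity analysis
#'
#' Re-runs the deterministic model with each parameter set to the bounds
#' of its uncertainty range while all others stay at base case, and
#' records the incremental net monetary benefit at both bounds. Ranges
#' are taken from `params$dsa`: hazard ratio at its 95% CI, rituximab
#' cost at +/- 30%, discounting at 0-5%, monthly state costs and one-time
#' immunoglobulin costs at their 95% CI limits, and - for the QALY
#' variant - the three state utilities at their CI limits.
#'
#' @param schedule A [build_schedule()] result.
#' @param params A [model_params()].
#' @param wtp Willingness-to-pay for the INMB, euros per effect unit.
#' @param effect `"ly"` or `"qaly"`; utilities are only varied for
#'   `"qaly"`.
#' @return A tibble of class `tornado_result`, one row per parameter:
#'   `parameter`, `low`, `high` (input bounds), `inmb_low`, `inmb_high`,
#'   `inmb_base`, `width`, sorted by decreasing `width`.
#' @examples
#' trial <- simulate_trial(trial_config(n_per_arm = 100, seed = 3))
#' sched <- build_schedule(trial, model_params())
#' tornado(sched, model_params())
#' @export
tornado <- function(schedule, params, wtp = params$wtp,
                    effect = c("ly", "qaly")) {
  effect <- match.arg(effect)

  evaluate <- function(pars, sched) {
    ctl <- accumulate_outcomes(run_cohort(sched, "control"), pars,
                               "control")
    int <- accumulate_outcomes(run_cohort(sched, "intervention"), pars,
                               "intervention")
    compare_arms(ctl, int, wtp = wtp, effect = effect)$inmb
  }

  set_par <- function(pars, name, value) {
    sched <- schedule
    if (name == "hr") {
      pars$hr <- value
      sched$event$p_intervention <-
        apply_hazard_ratio(sched$event$p_control, value)
    } else if (startsWith(name, "ig_onetime_")) {
      pars$ig_onetime[[sub("^ig_onetime_", "", name)]] <- value
    } else if (startsWith(name, "utility_")) {
      pars$utilities[[sub("^utility_", "", name)]] <- value
    } else {
      pars[[name]] <- value
    }
    list(pars = pars, sched = sched)
  }

  ranges <- params$dsa
  if (effect == "ly") {
    ranges <- ranges[!startsWith(names(ranges), "utility_")]
  }
  inmb_base <- evaluate(params, schedule)

  rows <- purrr::imap_dfr(ranges, function(bounds, name) {
    lo <- set_par(params, name, bounds[1])
    hi <- set_par(params, name, bounds[2])
    tibble(parameter = name, low = bounds[1], high = bounds[2],
           inmb_low = evaluate(lo$pars, lo$sched),
           inmb_high = evaluate(hi$pars, hi$sched))
  })
  out <- rows |>
    mutate(inmb_base = inmb_base,
           width = abs(.data$inmb_high - .data$inmb_low)) |>
    arrange(dplyr::desc(.data$width))
  class(out) <- c("tornado_result", class(out))
  out
}
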