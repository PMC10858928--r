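#' Build the per-cycle transition schedule from patient-level data
#'
#' Estimates every time-varying transition probability the cohort model
#' needs, from Kaplan-Meier analyses of a two-arm trial:
#'
#' * Event-free to Event/Post-event: KM of time to first event (deaths
#'   censored) in the control arm, converted per cycle with
#'   [cycle_probability()]; the intervention arm is obtained by applying
#'   the event-free-survival hazard ratio via [apply_hazard_ratio()].
#' * Event-free to Death: KM of time to event-free death (events censored),
#'   estimated per arm, or pooled across arms when `pool_ef_death = TRUE`.
#' * Event/Post-event to Death: KM of post-event survival measured from
#'   event onset, pooled across arms (the base case, because events are
#'   few) or per arm when `split_pe_death = TRUE`; indexed by tunnel age.
#'
#' Event transitions are structurally zero after cycle 18 (every first
#' event occurs within 18 months), and both tunnel clocks exit to the
#' absorbing Cured state with probability 1 at 18 months, so only cycles
#' 1-18 (and tunnel ages 0-17) carry estimated probabilities. Each
#' estimated probability also carries beta shape parameters
#' ([beta_uncertainty()]) for probabilistic sensitivity analysis; cycles
#' whose risk set is exhausted keep a fixed zero probability with `NA`
#' shapes.
#'
#' @param trial A `trial_data` object (or any list with a `patients`
#'   tibble holding `arm`, `t_event`, `event`, `t_death`, `death`,
#'   `t_censor`).
#' @param params A [model_params()]; supplies the hazard ratio.
#' @param horizon_cycles Model horizon in monthly cycles (36 base case,
#'   120 for the 10-year sensitivity analysis).
#' @param pool_ef_death Estimate the event-free death transition combining
#'   both arms.
#' @param split_pe_death Estimate the post-event death transition per arm
#'   instead of pooled.
#' @return An object of class `transition_schedule`: tibbles `event`
#'   (cycle, p_control, p_intervention, shape1, shape2), `death_ef`
#'   (cycle, arm, p, shape1, shape2), `death_pe` (age, arm, p, shape1,
#'   shape2), plus `hr`, `horizon_cycles`, `cure_cycle = 18` and the
#'   variant flags.
#' @examples
#' trial <- simulate_trial(trial_config(n_per_arm = 100, seed = 3))
#' sched <- build_schedule(trial, model_params())
#' head(sched$event)
#' @export
build_schedule <- function(trial, params, horizon_cycles = 36L,
                           pool_ef_death = FALSE, split_pe_death = FALSE) {
  p <- trial$patients
  stopifnot(all(c("control", "intervention") %in% p$arm))
  hr <- params$hr

  ctl <- dplyr::filter(p, .data$arm == "control")
  if (sum(ctl$event) == 0) {
    warn("No events in the control arm: the event schedule is degenerate.")
  }

  # time to first event, censoring death and administrative follow-up end
  efs_time <- function(d) {
    ifelse(d$event == 1, d$t_event,
           pmin(ifelse(d$death == 1, d$t_death, Inf), d$t_censor))
  }
  ev_curve <- km_curve(efs_time(ctl), ctl$event)
  cycles <- seq_len(CURE_MONTHS)
  ev <- schedule_rows(ev_curve, cycles)
  event <- tibble(cycle = cycles,
                  p_control = ev$p,
                  p_intervention = apply_hazard_ratio(ev$p, hr),
                  shape1 = ev$shape1, shape2 = ev$shape2)

  # event-free death: death censoring events
  efd_inputs <- function(d) {
    list(time = ifelse(d$event == 1, d$t_event,
                       ifelse(d$death == 1, d$t_death, d$t_censor)),
         status = as.integer(d$death == 1 & d$event == 0))
  }
  death_ef <- if (pool_ef_death) {
    x <- efd_inputs(p)
    rows <- schedule_rows(km_curve(x$time, x$status), cycles)
    bind_rows(
      dplyr::bind_cols(tibble(cycle = cycles, arm = "control"), rows),
      dplyr::bind_cols(tibble(cycle = cycles, arm = "intervention"), rows)
    )
  } else {
    purrr::map_dfr(c("control", "intervention"), function(a) {
      x <- efd_inputs(dplyr::filter(p, .data$arm == a))
      dplyr::bind_cols(tibble(cycle = cycles, arm = a),
                       schedule_rows(km_curve(x$time, x$status), cycles))
    })
  }

  # post-event death: survival from event onset, by tunnel age
  pe_inputs <- function(d) {
    d <- dplyr::filter(d, .data$event == 1)
    list(time = ifelse(d$death == 1, d$t_death, d$t_censor) - d$t_event,
         status = d$death)
  }
  # with no observed events the post-event KM is undefined; fall back to a
  # zero-risk tunnel with no sampled uncertainty
  zero_rows <- function() {
    tibble(p = rep(0, CURE_MONTHS), shape1 = NA_real_, shape2 = NA_real_)
  }
  pe_rows <- function(x) {
    if (length(x$time) == 0) zero_rows()
    else schedule_rows(km_curve(x$time, x$status), seq_len(CURE_MONTHS))
  }
  ages <- 0:(CURE_MONTHS - 1)
  death_pe <- if (split_pe_death) {
    purrr::map_dfr(c("control", "intervention"), function(a) {
      x <- pe_inputs(dplyr::filter(p, .data$arm == a))
      dplyr::bind_cols(tibble(age = ages, arm = a), pe_rows(x))
    })
  } else {
    dplyr::bind_cols(tibble(age = ages, arm = "pooled"),
                     pe_rows(pe_inputs(p)))
  }

  structure(
    list(event = event, death_ef = death_ef, death_pe = death_pe,
         hr = hr, horizon_cycles = as.integer(horizon_cycles),
         cure_cycle = CURE_MONTHS,
         pool_ef_death = pool_ef_death, split_pe_death = split_pe_death),
    class = "transition_schedule"
  )
}

# Per-cycle probabilities and beta shapes from one KM curve. Cycle k spans
# (k-1, k] months. Cycles whose risk set is empty keep the flat-curve
# probability (0) and NA shapes, i.e. no sampled uncertainty.
schedule_rows <- function(curve, cycles) {
  purrr::map_dfr(cycles, function(k) {
    n <- km_risk_at(curve, k - 1)
    if (n == 0) {
      return(tibble(p = 0, shape1 = NA_real_, shape2 = NA_real_))
    }
    sh <- beta_uncertainty(curve, k)
    tibble(p = cycle_probability(curve, k),
           shape1 = sh[["shape1"]], shape2 = sh[["shape2"]])
  })
}

# Accessors: per-cycle probability vectors for one arm ------------------

sched_p_event <- function(schedule, arm) {
  if (arm == "control") schedule$event$p_control
  else schedule$event$p_intervention
}

sched_p_death_ef <- function(schedule, arm) {
  dplyr::filter(schedule$death_ef, .data$arm == !!arm)$p
}

sched_p_death_pe <- function(schedule, arm) {
  d <- schedule$death_pe
  a <- if ("pooled" %in% d$arm) "pooled" else arm
  dplyr::filter(d, .data$arm == !!a)$p
}

#' @export
print.transition_schedule <- function(x, ...) {
  cat(sprintf(
    "<transition_schedule> %d cycles, cure at %d months, HR %.3f\n",
    x$horizon_cycles, x$cure_cycle, x$hr))
  cat(sprintf("  event-free death: %s | post-event death: %s\n",
              if (x$pool_ef_death) "pooled" else "per arm",
              if (x$split_pe_death) "per arm" else "pooled"))
  invisible(x)
}

#' Flatten a transition schedule to one long tibble
#'
#' @param x A `transition_schedule`.
#' @param ... Unused.
#' @return A tibble with columns `transition`, `arm`, `index` (cycle or
#'   tunnel age), `p`, `shape1`, `shape2`.
#' @export
tidy.transition_schedule <- function(x, ...) {
  bind_rows(
    tibble(transition = "event", arm = "control", index = x$event$cycle,
           p = x$event$p_control, shape1 = x$event$shape1,
           shape2 = x$event$shape2),
    tibble(transition = "event", arm = "intervention",
           index = x$event$cycle, p = x$event$p_intervention,
           shape1 = NA_real_, shape2 = NA_real_),
    tibble(transition = "death_event_free", arm = x$death_ef$arm,
           index = x$death_ef$cycle, p = x$death_ef$p,
           shape1 = x$death_ef$shape1, shape2 = x$death_ef$shape2),
    tibble(transition = "death_post_event", arm = x$death_pe$arm,
           index = x$death_pe$age, p = x$death_pe$p,
           shape1 = x$death_pe$shape1, shape2 = x$death_pe$shape2)
  )
}
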