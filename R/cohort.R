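# Numeric core of the cohort engine. Returns end-of-cycle occupancy for
# cycles 0..H: ef (event-free), pe (tunnel occupancy, H+1 x 18 matrix by
# age 0..17), cured, dead. Within a cycle: tunnel occupants age first
# (death by tunnel age, survivors advance, age-18 completers cured), then
# event-free occupants face death, then the event among survivors; new
# tunnel entrants join at age 0 and are first at risk next cycle; the
# event-free clock reaching 18 months sends survivors to Cured.
cohort_core <- function(p_event, p_death_ef, p_death_pe, H) {
  nt <- CURE_MONTHS
  ef <- numeric(H + 1); cured <- numeric(H + 1); dead <- numeric(H + 1)
  pe <- matrix(0, H + 1, nt)
  ef[1] <- 1

  for (k in seq_len(H)) {
    pe_prev <- pe[k, ]
    pe_die <- pe_prev * p_death_pe
    pe_adv <- pe_prev - pe_die
    dead[k + 1] <- dead[k] + sum(pe_die)
    cured[k + 1] <- cured[k] + pe_adv[nt]   # 18 tunnel months completed
    pe[k + 1, ] <- c(0, pe_adv[-nt])

    e <- ef[k]
    if (e > 0 && k <= nt) {
      p_d <- p_death_ef[k]; p_e <- p_event[k]
      dead[k + 1] <- dead[k + 1] + e * p_d
      pe[k + 1, 1] <- pe[k + 1, 1] + e * (1 - p_d) * p_e
      e <- e * (1 - p_d) * (1 - p_e)
      if (k == nt) {                        # 18 event-free months completed
        cured[k + 1] <- cured[k + 1] + e
        e <- 0
      }
    }
    ef[k + 1] <- e
  }
  list(ef = ef, pe = pe, cured = cured, dead = dead, H = H)
}

core_to_trace <- function(core, arm) {
  nt <- CURE_MONTHS
  H <- core$H
  cycles <- 0:H
  trace <- bind_rows(
    tibble(cycle = cycles, state = "event_free", clock = pmin(cycles, nt),
           occupancy = core$ef),
    purrr::map_dfr(seq_len(nt), function(j) {
      tibble(cycle = cycles, state = "post_event", clock = j - 1L,
             occupancy = core$pe[, j])
    }),
    tibble(cycle = cycles, state = "cured", clock = NA_integer_,
           occupancy = core$cured),
    tibble(cycle = cycles, state = "dead", clock = NA_integer_,
           occupancy = core$dead)
  ) |> arrange(.data$cycle, .data$state, .data$clock)
  structure(trace, arm = arm, horizon_cycles = H,
            class = c("cohort_trace", class(trace)))
}

sched_probs <- function(schedule, arm) {
  list(p_event = sched_p_event(schedule, arm),
       p_death_ef = sched_p_death_ef(schedule, arm),
       p_death_pe = sched_p_death_pe(schedule, arm))
}

#' Run the semi-Markov cohort simulation for one arm
#'
#' Propagates a cohort (occupancy 1 in Event-free at cycle 0) through the
#' four-state model in monthly cycles. Within each cycle, Event-free
#' occupants face death first and then the event among survivors (so
#' `P(event this cycle) = (1 - p_death) * p_event`); Event/Post-event
#' occupants at tunnel age `j` face the age-specific death probability and
#' otherwise advance one month; new tunnel entrants join at age 0 and are
#' first at risk of post-event death in the following cycle. Survivors
#' completing 18 months in Event-free, or 18 months in the tunnel, move to
#' the absorbing Cured state with probability 1. No background mortality
#' is applied and no half-cycle correction is used; snapshots record
#' occupancy at cycle end.
#'
#' @param schedule A [build_schedule()] result.
#' @param arm `"control"` or `"intervention"`.
#' @param horizon_cycles Number of monthly cycles; defaults to the
#'   schedule's horizon.
#' @return A `cohort_trace`: tibble with columns `cycle` (0..horizon),
#'   `state` (`event_free`, `post_event`, `cured`, `dead`), `clock`
#'   (months in state: the Event-free clock, or tunnel age; `NA` for
#'   absorbing states) and `occupancy`; attributes `arm` and
#'   `horizon_cycles`.
#' @examples
#' trial <- simulate_trial(trial_config(n_per_arm = 100, seed = 3))
#' sched <- build_schedule(trial, model_params())
#' trace <- run_cohort(sched, "control")
#' head(state_occupancy(trace))
#' @export
run_cohort <- function(schedule, arm,
                       horizon_cycles = schedule$horizon_cycles) {
  pr <- sched_probs(schedule, arm)
  check_exit_probs(pr$p_event, pr$p_death_ef, pr$p_death_pe)
  core <- cohort_core(pr$p_event, pr$p_death_ef, pr$p_death_pe,
                      as.integer(horizon_cycles))
  core_to_trace(core, arm)
}

check_exit_probs <- function(p_event, p_death_ef, p_death_pe) {
  stopifnot(length(p_event) == CURE_MONTHS,
            length(p_death_ef) == CURE_MONTHS,
            length(p_death_pe) == CURE_MONTHS)
  probs <- c(p_event, p_death_ef, p_death_pe)
  if (anyNA(probs) || any(probs < 0 | probs > 1)) {
    abort("Transition probabilities must lie in [0, 1].")
  }
  # with the death-first competing-decrement ordering, the total exit
  # probability p_d + (1 - p_d) * p_e never exceeds 1
  invisible(TRUE)
}

#' Individual-level microsimulation of the same transition rules
#'
#' Simulates `n_patients` monthly trajectories under exactly the precedence
#' rules of [run_cohort()] (death before event within a cycle, tunnel aging
#' before new entrants, cure at 18 months) and averages state occupancy.
#' This is a validation oracle: the cohort trace is its exact expectation,
#' so the two must agree within binomial Monte Carlo error.
#'
#' @inheritParams run_cohort
#' @param n_patients Number of simulated patients.
#' @param seed Integer seed; the result is deterministic given it.
#' @return A `cohort_trace` in the same format as [run_cohort()].
#' @export
microsim_cohort <- function(schedule, arm, n_patients, seed,
                            horizon_cycles = schedule$horizon_cycles) {
  stopifnot(n_patients >= 1)
  pr <- sched_probs(schedule, arm)
  check_exit_probs(pr$p_event, pr$p_death_ef, pr$p_death_pe)
  H <- as.integer(horizon_cycles)
  nt <- CURE_MONTHS
  n <- as.integer(n_patients)

  local_seed(seed, {
    # states: 0 event-free, 1 post-event, 2 cured, 3 dead
    state <- integer(n)
    age <- integer(n)  # tunnel age for post-event patients

    core <- list(ef = numeric(H + 1), pe = matrix(0, H + 1, nt),
                 cured = numeric(H + 1), dead = numeric(H + 1), H = H)
    record <- function(k) {
      core$ef[k + 1] <<- mean(state == 0L)
      core$pe[k + 1, ] <<- tabulate(age[state == 1L] + 1L, nbins = nt) / n
      core$cured[k + 1] <<- mean(state == 2L)
      core$dead[k + 1] <<- mean(state == 3L)
    }
    record(0L)

    for (k in seq_len(H)) {
      in_pe <- state == 1L
      if (any(in_pe)) {
        die <- in_pe & runif(n) < pr$p_death_pe[age + 1L]
        state[die] <- 3L
        adv <- state == 1L
        age[adv] <- age[adv] + 1L
        state[adv & age >= nt] <- 2L
      }
      in_ef <- state == 0L
      if (any(in_ef) && k <= nt) {
        die <- in_ef & runif(n) < pr$p_death_ef[k]
        state[die] <- 3L
        ev <- state == 0L & in_ef & runif(n) < pr$p_event[k]
        state[ev] <- 1L
        age[ev] <- 0L
        if (k == nt) state[state == 0L] <- 2L
      }
      record(k)
    }
    core_to_trace(core, arm)
  })
}

#' Total occupancy per state and cycle
#'
#' Collapses a `cohort_trace` over tunnel substates.
#'
#' @param trace A `cohort_trace`.
#' @return A tibble `cycle`, `state`, `occupancy`.
#' @export
state_occupancy <- function(trace) {
  trace |>
    group_by(.data$cycle, .data$state) |>
    summarise(occupancy = sum(.data$occupancy), .groups = "drop")
}

# occupancy at the START of each cycle 1..H (the state occupied during the
# month), plus entrants into Cured at the end of each cycle; used by the
# accumulation stage
start_of_cycle_occupancy <- function(trace) {
  H <- attr(trace, "horizon_cycles")
  occ <- state_occupancy(trace) |>
    tidyr::pivot_wider(names_from = "state", values_from = "occupancy") |>
    arrange(.data$cycle)
  list(ef = occ$event_free[seq_len(H)],
       pe = occ$post_event[seq_len(H)],
       cured = occ$cured[seq_len(H)],
       dead = occ$dead[seq_len(H)],
       cured_entrants = diff(occ$cured))
}

# same quantities straight from a cohort_core result (fast PSA path)
start_occ_from_core <- function(core) {
  H <- core$H
  idx <- seq_len(H)
  list(ef = core$ef[idx], pe = rowSums(core$pe)[idx],
       cured = core$cured[idx], dead = core$dead[idx],
       cured_entrants = diff(core$cured))
}
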