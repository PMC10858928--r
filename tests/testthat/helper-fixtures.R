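# Hand-built transition schedules for engine tests: fixed per-cycle
# probability vectors (recycled to the 18 estimated cycles/ages), no
# sampling uncertainty attached.
manual_schedule <- function(p_event = 0, p_event_int = NULL,
                            p_death_ef = 0, p_death_ef_int = NULL,
                            p_death_pe = 0, hr = 1, horizon = 36L) {
  nt <- 18L
  pe_ctl <- rep_len(p_event, nt)
  pe_int <- if (is.null(p_event_int)) 1 - (1 - pe_ctl)^hr
            else rep_len(p_event_int, nt)
  def_ctl <- rep_len(p_death_ef, nt)
  def_int <- if (is.null(p_death_ef_int)) def_ctl
             else rep_len(p_death_ef_int, nt)
  na <- rep(NA_real_, nt)
  structure(
    list(
      event = tibble::tibble(cycle = 1:nt, p_control = pe_ctl,
                             p_intervention = pe_int,
                             shape1 = na, shape2 = na),
      death_ef = dplyr::bind_rows(
        tibble::tibble(cycle = 1:nt, arm = "control", p = def_ctl,
                       shape1 = na, shape2 = na),
        tibble::tibble(cycle = 1:nt, arm = "intervention", p = def_int,
                       shape1 = na, shape2 = na)
      ),
      death_pe = tibble::tibble(age = 0:(nt - 1), arm = "pooled",
                                p = rep_len(p_death_pe, nt),
                                shape1 = na, shape2 = na),
      hr = hr, horizon_cycles = as.integer(horizon), cure_cycle = nt,
      pool_ef_death = FALSE, split_pe_death = FALSE
    ),
    class = "transition_schedule"
  )
}

# random but valid schedule (probabilities small enough to be realistic)
random_schedule <- function(seed, horizon = 36L) {
  set.seed(seed)
  manual_schedule(
    p_event = runif(18, 0, 0.08),
    p_event_int = runif(18, 0, 0.05),
    p_death_ef = runif(18, 0, 0.03),
    p_death_ef_int = runif(18, 0, 0.03),
    p_death_pe = runif(18, 0, 0.10),
    horizon = horizon
  )
}

# parameters stripped of cost/utility asymmetries: identical arms give
# exactly zero incremental effect and cost
symmetric_params <- function(...) {
  model_params(
    monthly_cost_ef_control = 3000, monthly_cost_ef_intervention = 3000,
    rituximab_cost = 0,
    ig_onetime = c(ef_control = 300, ef_intervention = 300, cured = 400),
    ...
  )
}

small_trial <- function(n = 80, seed = 11, ...) {
  simulate_trial(trial_config(n_per_arm = n, seed = seed, ...))
}

max_occupancy_gap <- function(trace_a, trace_b) {
  a <- dplyr::arrange(trace_a, cycle, state, clock)
  b <- dplyr::arrange(trace_b, cycle, state, clock)
  max(abs(a$occupancy - b$occupancy))
}
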