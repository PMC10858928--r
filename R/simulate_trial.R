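# Event-time law of the synthetic trial
# -------------------------------------
# Control-arm event-free survival is a mixture cure model
#   S_ctl(t) = pi + (1 - pi) * S_T(t),
# with S_T the survival of an exponential(rate) truncated to (0, 18]
# months, so every generated first event occurs within 18 months of
# randomization -- the structural assumption of the cohort model.
# Intervention-arm event times are drawn from S_int(t) = S_ctl(t)^HR,
# i.e. exact marginal proportional hazards, so a Kaplan-Meier /
# Nelson-Aalen hazard-ratio estimate on large samples recovers HR.

# Survival of exponential(rate) truncated to (0, upper].
trunc_exp_surv <- function(t, rate, upper = CURE_MONTHS) {
  s <- (exp(-rate * t) - exp(-rate * upper)) / (1 - exp(-rate * upper))
  ifelse(t >= upper, 0, pmax(s, 0))
}

# Inverse of trunc_exp_surv: t such that S_T(t) = s, s in [0, 1].
trunc_exp_surv_inv <- function(s, rate, upper = CURE_MONTHS) {
  -log(s * (1 - exp(-rate * upper)) + exp(-rate * upper)) / rate
}

# Draw n event times from the marginal S_ctl(t)^hr (hr = 1 for control).
# Returns Inf for cured (never-event) patients.
draw_event_times <- function(n, pi_cure, rate, hr) {
  if (rate <= 0 || pi_cure >= 1) return(rep(Inf, n))
  u <- runif(n)
  s_ctl <- u^(1 / hr)                    # solve S_ctl(t)^hr = u
  t <- rep(Inf, n)
  has_event <- s_ctl > pi_cure           # below pi_cure the patient is cured
  frac <- (s_ctl[has_event] - pi_cure) / (1 - pi_cure)
  t[has_event] <- trunc_exp_surv_inv(frac, rate)
  t
}

#' Simulate patient-level two-arm trial data
#'
#' Generates a synthetic randomized trial with the statistical structure the
#' cost-effectiveness model assumes: a cured majority, all first events
#' within 18 months, a proportional-hazards event-rate reduction in the
#' intervention arm, competing event-free death, post-event death measured
#' from event onset, and administrative censoring. Latent times are drawn
#' per patient and reduced to the observed record (time of first event,
#' time of death, censoring time, event/death indicators).
#'
#' @param config A [trial_config()].
#' @return An object of class `trial_data`: a list with `patients` (one row
#'   per patient), `costs` (empty until [simulate_cost_records()] is called)
#'   and the generating `config`. `patients` columns: `id`, `arm`
#'   (`"control"`/`"intervention"`), `t_event` (months, `NA` if no event
#'   observed), `event` (0/1), `t_death` (`NA` if alive at censoring),
#'   `death` (0/1), `t_censor`, `in_cost_subgroup`, `rituximab_mg`,
#'   `ig_grams_ef`, `ig_grams_cured`.
#' @examples
#' trial <- simulate_trial(trial_config(n_per_arm = 50, seed = 7))
#' table(trial$patients$arm, trial$patients$event)
#' @export
simulate_trial <- function(config) {
  stopifnot(inherits(config, "trial_config"))
  local_seed(config$seed, {
    n <- config$n_per_arm
    pi_c <- config$cure_fraction_control
    arms <- rep(c("control", "intervention"), each = n)

    t_ev <- c(
      draw_event_times(n, pi_c, config$event_rate_control, hr = 1),
      draw_event_times(n, pi_c, config$event_rate_control, config$hr_event)
    )
    # latent event-free death and post-event survival
    d_ef <- if (config$death_event_free_rate > 0) {
      rexp(2 * n, config$death_event_free_rate)
    } else rep(Inf, 2 * n)
    d_pe <- if (config$death_after_event_rate > 0) {
      rexp(2 * n, config$death_after_event_rate)
    } else rep(Inf, 2 * n)

    cens <- config$admin_censor_months
    # resolve latent times into the observed record
    event_first <- t_ev < pmin(d_ef, cens)
    t_death_lat <- ifelse(event_first, t_ev + d_pe, d_ef)
    death_obs <- t_death_lat <= cens
    event_obs <- event_first  # events precede death by construction

    patients <- tibble(
      id = seq_len(2 * n),
      arm = arms,
      t_event = ifelse(event_obs, t_ev, NA_real_),
      event = as.integer(event_obs),
      t_death = ifelse(death_obs, t_death_lat, NA_real_),
      death = as.integer(death_obs),
      t_censor = cens
    )

    # cost subgroup: a simple random sample across both arms
    sub <- sample(patients$id, min(config$cost_subgroup_size, 2L * n))
    patients$in_cost_subgroup <- patients$id %in% sub

    # drug exposure: rituximab in the intervention arm only; one-time
    # immunoglobulin use assigned at the configured per-arm rates, plus
    # post-cure use among patients reaching the cured state
    patients$rituximab_mg <- ifelse(
      patients$arm == "intervention",
      rgamma(2 * n, shape = config$rituximab_mg_shape,
             rate = config$rituximab_mg_shape / config$rituximab_mg_mean),
      0
    )
    ig <- config$ig_rates
    p_ig <- ifelse(patients$arm == "control", ig$ef_control,
                   ig$ef_intervention)
    m_ig <- ifelse(patients$arm == "control", ig$mean_ef_control,
                   ig$mean_ef_intervention)
    use_ef <- rbinom(2 * n, 1, p_ig) == 1
    patients$ig_grams_ef <- ifelse(
      use_ef, rgamma(2 * n, shape = 4, rate = 4 / m_ig) / 40.43, 0)
    cured <- !event_obs & !death_obs & cens >= CURE_MONTHS |
      (event_obs & !death_obs & (cens - t_ev) >= CURE_MONTHS)
    use_cured <- cured & rbinom(2 * n, 1, ig$cured) == 1
    patients$ig_grams_cured <- ifelse(
      use_cured, rgamma(2 * n, shape = 4, rate = 4 / ig$mean_cured) / 40.43, 0)

    structure(
      list(patients = patients,
           costs = tibble(patient_id = integer(), month = integer(),
                          state = character(), amount_eur = double()),
           config = config),
      class = "trial_data"
    )
  })
}

#' Attach monthly hospitalization cost records to a synthetic trial
#'
#' For each patient in the cost subgroup, draws gamma-distributed monthly
#' hospital costs and labels each record with the health state it is
#' attributed to: event-free months run from randomization through month 18
#' or until 7 days before the first event, whichever comes first;
#' post-event months run from the event for at most 18 months. Only whole
#' months fully inside the attribution window generate a record, so the
#' downstream costing stage can re-derive unbiased per-state monthly means.
#'
#' @param trial A `trial_data` object from [simulate_trial()].
#' @param config Optional [trial_config()]; defaults to the one stored in
#'   `trial`.
#' @return `trial` with its `costs` tibble filled
#'   (`patient_id`, `month`, `state`, `amount_eur`).
#' @examples
#' trial <- simulate_trial(trial_config(n_per_arm = 50, seed = 7))
#' trial <- simulate_cost_records(trial)
#' dplyr::count(trial$costs, state)
#' @export
simulate_cost_records <- function(trial, config = trial$config) {
  stopifnot(inherits(trial, "trial_data"))
  sub <- dplyr::filter(trial$patients, .data$in_cost_subgroup)
  if (nrow(sub) == 0) abort("The cost subgroup is empty.")

  local_seed(config$seed + 1L, {
    window <- 7 / DAYS_PER_MONTH  # pre-event attribution window, months

    per_patient <- function(id, arm, t_event, t_death, t_censor) {
      end_alive <- min(t_death, t_censor, na.rm = TRUE)
      ef_end <- min(CURE_MONTHS,
                    if (!is.na(t_event)) max(0, t_event - window) else Inf,
                    end_alive)
      ef_months <- seq_len(max(0, floor(ef_end)))
      cp <- if (arm == "control") config$cost_params$ef_control
            else config$cost_params$ef_intervention
      ef <- if (length(ef_months)) {
        tibble(patient_id = id, month = as.integer(ef_months),
               state = "event_free",
               amount_eur = rgamma(length(ef_months), shape = cp$shape,
                                   rate = cp$shape / cp$mean))
      } else NULL
      pe <- NULL
      if (!is.na(t_event)) {
        pe_months_after <- seq_len(
          max(0, floor(min(CURE_MONTHS, end_alive - t_event))))
        if (length(pe_months_after)) {
          cpp <- config$cost_params$post_event
          pe <- tibble(patient_id = id,
                       month = as.integer(floor(t_event) + pe_months_after),
                       state = "post_event",
                       amount_eur = rgamma(length(pe_months_after),
                                           shape = cpp$shape,
                                           rate = cpp$shape / cpp$mean))
        }
      }
      bind_rows(ef, pe)
    }

    trial$costs <- purrr::pmap_dfr(
      list(sub$id, sub$arm, sub$t_event, sub$t_death, sub$t_censor),
      per_patient
    )
    trial
  })
}

#' @export
print.trial_data <- function(x, ...) {
  p <- x$patients
  cat(sprintf("<trial_data> %d patients (%d control / %d intervention)\n",
              nrow(p), sum(p$arm == "control"),
              sum(p$arm == "intervention")))
  cat(sprintf("  events: %d | deaths: %d | cost records: %d\n",
              sum(p$event), sum(p$death), nrow(x$costs)))
  invisible(x)
}

#' Write a synthetic trial to delimited files
#'
#' @param trial A `trial_data` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (`patients.csv`, `cost_records.csv`).
#' @export
write_trial_data <- function(trial, dir) {
  stopifnot(inherits(trial, "trial_data"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(patients = file.path(dir, "patients.csv"),
             costs = file.path(dir, "cost_records.csv"))
  utils::write.csv(trial$patients, paths["patients"], row.names = FALSE)
  utils::write.csv(trial$costs, paths["costs"], row.names = FALSE)
  invisible(paths)
}

#' Read a synthetic trial back from delimited files
#'
#' @param dir Directory holding `patients.csv` and `cost_records.csv`.
#' @param config Optional [trial_config()] to attach.
#' @return A `trial_data` object.
#' @export
read_trial_data <- function(dir, config = NULL) {
  patients <- as_tibble(utils::read.csv(file.path(dir, "patients.csv")))
  costs <- as_tibble(utils::read.csv(file.path(dir, "cost_records.csv")))
  structure(list(patients = patients, costs = costs, config = config),
            class = "trial_data")
}
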