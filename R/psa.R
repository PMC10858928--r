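# Moment-matched beta shapes for a utility with mean m and standard error
# s. Infeasible combinations (s^2 >= m(1-m)) have the SE clamped to 99% of
# the feasibility bound, with a message, rather than failing the draw.
beta_moments <- function(m, s) {
  if (m <= 0 || m >= 1) abort("Beta moment matching needs mean in (0, 1).")
  bound <- sqrt(m * (1 - m))
  if (s >= bound) {
    warn(sprintf(
      "Utility SE %.3f infeasible for mean %.2f; clamped to %.3f.",
      s, m, 0.99 * bound))
    s <- 0.99 * bound
  }
  k <- m * (1 - m) / s^2 - 1
  c(shape1 = m * k, shape2 = (1 - m) * k)
}

#' Draw one joint parameter set for probabilistic sensitivity analysis
#'
#' Samples every uncertain model parameter independently from its assigned
#' family: the hazard ratio from its log-normal, each cost from its gamma
#' (one-time immunoglobulin costs as fixed use-rate times a gamma-drawn
#' per-user cost), and each nonzero utility from a beta matched by method
#' of moments to mean and SE (20% of the mean by default). Transition
#' probabilities are sampled separately, per cycle, inside [run_psa()],
#' because their beta shapes live in the transition schedule.
#'
#' @param base A [model_params()].
#' @param sample Which components to draw; any subset of
#'   `c("hr", "costs", "utilities")`. Components not listed stay at their
#'   base values, so `sample = character(0)` returns `base` unchanged.
#' @return A `model_params` with the drawn values substituted.
#' @examples
#' set.seed(1)
#' sample_params(model_params())$hr
#' @export
sample_params <- function(base, sample = c("hr", "costs", "utilities")) {
  out <- base
  psa <- base$psa
  if ("hr" %in% sample) {
    out$hr <- rlnorm(1, psa$hr_lnorm[["meanlog"]], psa$hr_lnorm[["sdlog"]])
  }
  if ("costs" %in% sample) {
    g <- psa$gamma
    draw <- rgamma(nrow(g), shape = g[, "shape"], rate = g[, "rate"])
    names(draw) <- rownames(g)
    out$monthly_cost_ef_control <- draw[["monthly_cost_ef_control"]]
    out$monthly_cost_ef_intervention <-
      draw[["monthly_cost_ef_intervention"]]
    out$rituximab_cost <- draw[["rituximab_cost"]]
    out$monthly_cost_pe <- draw[["monthly_cost_pe"]]
    out$ig_onetime <- c(
      ef_control = psa$ig_rates[["ef_control"]] *
        draw[["ig_user_cost_ef_control"]],
      ef_intervention = psa$ig_rates[["ef_intervention"]] *
        draw[["ig_user_cost_ef_intervention"]],
      cured = psa$ig_rates[["cured"]] * draw[["ig_user_cost_cured"]]
    )
  }
  if ("utilities" %in% sample) {
    u <- base$utilities
    for (s in c("event_free", "post_event", "cured")) {
      sh <- beta_moments(u[[s]], psa$utility_se_frac * u[[s]])
      out$utilities[[s]] <- rbeta(1, sh[["shape1"]], sh[["shape2"]])
    }
  }
  out
}

# One sampled transition schedule: per-cycle independent beta draws where
# shapes are available (fixed point values elsewhere), with a single
# hazard-ratio draw mapped onto the sampled control event probabilities.
sample_schedule <- function(schedule, hr_draw) {
  draw_col <- function(p, shape1, shape2) {
    ok <- !is.na(shape1)
    p[ok] <- rbeta(sum(ok), shape1[ok], shape2[ok])
    p
  }
  out <- schedule
  out$event$p_control <- draw_col(schedule$event$p_control,
                                  schedule$event$shape1,
                                  schedule$event$shape2)
  out$event$p_intervention <- apply_hazard_ratio(out$event$p_control,
                                                 hr_draw)
  out$death_ef$p <- draw_col(schedule$death_ef$p, schedule$death_ef$shape1,
                             schedule$death_ef$shape2)
  out$death_pe$p <- draw_col(schedule$death_pe$p, schedule$death_pe$shape1,
                             schedule$death_pe$shape2)
  out$hr <- hr_draw
  out
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo propagation of parameter uncertainty: per simulation, one
#' joint draw of hazard ratio, costs and (for the QALY variant) utilities
#' via [sample_params()], plus per-cycle beta draws of every estimated
#' transition probability; both cohorts are re-run and the incremental
#' outcomes recorded. Summaries are percentile-based, and the
#' cost-effectiveness acceptability curve gives, for each willingness-to-
#' pay on the grid, the fraction of draws with positive incremental net
#' monetary benefit. Draws whose model evaluation fails are dropped and
#' counted, never silently resampled.
#'
#' @param schedule A [build_schedule()] result.
#' @param params A [model_params()].
#' @param n_sims Number of Monte Carlo simulations (10,000 for the full
#'   analysis).
#' @param seed Integer seed; results are reproducible given it.
#' @param effect `"ly"` (utilities held fixed) or `"qaly"` (utilities
#'   sampled).
#' @param wtp_grid Willingness-to-pay grid for the acceptability curve.
#' @param sample Components passed to [sample_params()]; defaults to
#'   `c("hr", "costs")`, plus `"utilities"` for the QALY variant.
#' @param sample_transitions Draw per-cycle transition probabilities from
#'   their beta distributions; with `FALSE` and `sample = character(0)`
#'   every draw reproduces the deterministic base case.
#' @return An object of class `psa_result`: `draws` (one row per
#'   simulation: per-arm effects and costs, `delta_e`, `delta_c`, `inmb`),
#'   `ceac` (`wtp`, `prob_cost_effective`), `summary` (mean and percentile
#'   95% CI per quantity), `n_sims`, `n_skipped`, `seed`, `wtp`, `effect`.
#' @examples
#' trial <- simulate_trial(trial_config(n_per_arm = 100, seed = 3))
#' sched <- build_schedule(trial, model_params())
#' psa <- run_psa(sched, model_params(), n_sims = 50, seed = 9)
#' glance(psa)
#' @export
run_psa <- function(schedule, params, n_sims = 10000, seed = 1,
                    effect = c("ly", "qaly"),
                    wtp_grid = params$wtp_grid, sample = NULL,
                    sample_transitions = TRUE) {
  effect <- match.arg(effect)
  stopifnot(n_sims >= 1)
  sample_what <- sample %||%
    if (effect == "qaly") c("hr", "costs", "utilities")
    else c("hr", "costs")
  H <- round(params$horizon_years * 12)

  local_seed(seed, {
    one_sim <- function(i) {
      pars <- sample_params(params, sample_what)
      sch <- if (sample_transitions) sample_schedule(schedule, pars$hr)
        else {
          s2 <- schedule
          s2$event$p_intervention <-
            apply_hazard_ratio(s2$event$p_control, pars$hr)
          s2
        }
      per_arm <- lapply(c("control", "intervention"), function(a) {
        pr <- sched_probs(sch, a)
        accumulate_from_occ(
          start_occ_from_core(
            cohort_core(pr$p_event, pr$p_death_ef, pr$p_death_pe, H)),
          pars, a)
      })
      ctl <- per_arm[[1]]; int <- per_arm[[2]]
      e_ctl <- ctl[[effect]]; e_int <- int[[effect]]
      c(e_control = e_ctl, e_intervention = e_int,
        c_control = ctl$cost, c_intervention = int$cost,
        delta_e = e_int - e_ctl, delta_c = int$cost - ctl$cost)
    }

    n_skipped <- 0L
    draws <- purrr::map(seq_len(n_sims), function(i) {
      tryCatch(one_sim(i), error = function(e) {
        n_skipped <<- n_skipped + 1L
        NULL
      })
    })
    draws <- do.call(rbind, purrr::compact(draws))
    draws <- as_tibble(draws)
    draws$sim <- seq_len(nrow(draws))
    draws$inmb <- params$wtp * draws$delta_e - draws$delta_c
    draws <- select(draws, "sim", dplyr::everything())

    ceac <- tibble(
      wtp = wtp_grid,
      prob_cost_effective = purrr::map_dbl(
        wtp_grid, ~ mean(.x * draws$delta_e - draws$delta_c > 0))
    )

    qs <- function(x) c(mean = mean(x), lower = unname(quantile(x, 0.025)),
                        upper = unname(quantile(x, 0.975)))
    summary <- purrr::map_dfr(
      c("e_control", "e_intervention", "c_control", "c_intervention",
        "delta_e", "delta_c", "inmb"),
      function(v) tibble(quantity = v, !!!as.list(qs(draws[[v]])))
    )

    if (n_skipped > 0) {
      warn(sprintf("%d of %d PSA draws failed and were dropped.",
                   n_skipped, n_sims))
    }
    structure(
      list(draws = draws, ceac = ceac, summary = summary,
           n_sims = as.integer(n_sims), n_skipped = n_skipped,
           seed = as.integer(seed), wtp = params$wtp, effect = effect),
      class = "psa_result"
    )
  })
}

#' Probability cost-effective at a willingness-to-pay
#'
#' Re-computes the acceptability-curve ordinate from the persisted draw
#' table: the fraction of simulations with `wtp * delta_e - delta_c > 0`.
#'
#' @param psa A `psa_result`.
#' @param wtp Willingness-to-pay value(s).
#' @return Probability (vectorized over `wtp`).
#' @export
prob_cost_effective <- function(psa, wtp = psa$wtp) {
  vapply(wtp, function(l) mean(l * psa$draws$delta_e - psa$draws$delta_c > 0),
         numeric(1))
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %d simulations (%d dropped), effect = %s\n",
              x$n_sims, x$n_skipped, toupper(x$effect)))
  s <- x$summary
  de <- s[s$quantity == "delta_e", ]; dc <- s[s$quantity == "delta_c", ]
  cat(sprintf("  dE = %.3f [%.3f; %.3f] | dC = %.0f [%.0f; %.0f] EUR\n",
              de$mean, de$lower, de$upper, dc$mean, dc$lower, dc$upper))
  cat(sprintf("  P(cost-effective at %s EUR) = %.1f%%\n",
              format(x$wtp, big.mark = ","),
              100 * prob_cost_effective(x)))
  invisible(x)
}
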