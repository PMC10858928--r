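#' Kaplan-Meier curve as a tidy table
#'
#' Product-limit estimate of a survival function, with Greenwood standard
#' errors, wrapped as a tibble keyed by event time. Ties between events and
#' censorings at the same time follow the usual convention: events are
#' counted before censored subjects leave the risk set.
#'
#' @param times Follow-up times (months), non-negative.
#' @param status Event indicator, 0 = censored, 1 = event.
#' @return A tibble of class `km_curve` with columns `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv`, `greenwood_se`, one row per distinct
#'   observed time, beginning with the implicit `(0, 1)` origin row.
#' @examples
#' km_curve(c(3, 5, 5, 8), c(1, 1, 0, 1))
#' @export
km_curve <- function(times, status) {
  if (length(times) == 0) abort("Empty input: no survival times.")
  if (any(times < 0)) abort("Survival times must be non-negative.")
  if (!all(status %in% c(0, 1))) abort("`status` must be binary 0/1.")
  fit <- survival::survfit(survival::Surv(times, status) ~ 1,
                           conf.type = "none")
  out <- tibble(
    time = c(0, fit$time),
    n_risk = c(length(times), fit$n.risk),
    n_event = c(0, fit$n.event),
    n_censor = c(0, fit$n.censor),
    surv = c(1, fit$surv),
    # survfit's std.err is on log S; Greenwood SE of S itself is S * se(log S)
    greenwood_se = c(0, fit$surv * fit$std.err)
  )
  class(out) <- c("km_curve", class(out))
  out
}

# Step-function evaluation S(t): right-continuous, flat between event
# times and beyond the last observed time.
km_surv_at <- function(curve, t) {
  idx <- findInterval(t, curve$time)
  ifelse(idx == 0, 1, curve$surv[pmax(idx, 1L)])
}

# Number at risk at the start of the interval (t, t+u]: subjects whose
# observed time exceeds t. Used for the per-cycle beta parameterization.
km_risk_at <- function(curve, t) {
  keep <- curve$time > t
  if (!any(keep)) return(0L)
  as.integer(curve$n_risk[which(keep)[1]])
}

# Events observed in (t_lo, t_hi].
km_events_in <- function(curve, t_lo, t_hi) {
  as.integer(sum(curve$n_event[curve$time > t_lo & curve$time <= t_hi]))
}

#' Cycle-specific transition probability from a survival curve
#'
#' Converts a survival function into the conditional probability of the
#' event during one model cycle: `1 - S(t) / S(t - u)`, the chance of the
#' transition in `(t - u, t]` given event-free survival to `t - u`.
#'
#' @param curve A [km_curve()].
#' @param t End of the cycle (months).
#' @param u Cycle length (months), default 1.
#' @return A probability in \[0, 1\].
#' @examples
#' cv <- km_curve(c(3, 5, 5, 8), c(1, 1, 0, 1))
#' cycle_probability(cv, t = 4)   # event risk in month (3, 4]
#' @export
cycle_probability <- function(curve, t, u = 1) {
  s_prev <- km_surv_at(curve, t - u)
  if (any(s_prev == 0)) {
    abort(paste("S(t - u) = 0: the conditional transition probability is",
                "undefined (risk set exhausted)."))
  }
  p <- 1 - km_surv_at(curve, t) / s_prev
  pmin(pmax(p, 0), 1)
}

#' Apply a hazard ratio to a per-cycle probability
#'
#' Transforms a control-arm cycle probability onto the intervention arm
#' under proportional hazards: `1 - (1 - p)^hr`. With `p = 1` the result is
#' 1 for any positive `hr` (a certain transition stays certain).
#'
#' @param p_control Control-arm per-cycle probability, in \[0, 1\].
#' @param hr Hazard ratio, positive.
#' @return The intervention-arm probability.
#' @examples
#' apply_hazard_ratio(0.10, 0.317)
#' @export
apply_hazard_ratio <- function(p_control, hr) {
  stopifnot(all(hr > 0), all(p_control >= 0), all(p_control <= 1))
  1 - (1 - p_control)^hr
}

#' Beta uncertainty for a per-cycle transition probability
#'
#' Parameterizes probabilistic-sensitivity-analysis uncertainty of one
#' cycle's transition probability as a beta distribution built from the
#' Kaplan-Meier risk set of that cycle, with a Jeffreys 1/2 continuity
#' adjustment so cycles with zero observed events still carry uncertainty:
#' `shape1 = d + 1/2`, `shape2 = n - d + 1/2` for `d` events among `n` at
#' risk.
#'
#' @param curve A [km_curve()].
#' @param cycle Cycle index `k`; the cycle spans `(k - 1, k]` months.
#' @param u Cycle length in months, default 1.
#' @return Named numeric vector `c(shape1 = , shape2 = )`.
#' @examples
#' cv <- km_curve(c(3, 5, 5, 8), c(1, 1, 0, 1))
#' beta_uncertainty(cv, cycle = 4)
#' @export
beta_uncertainty <- function(curve, cycle, u = 1) {
  n <- km_risk_at(curve, (cycle - 1) * u)
  if (n == 0) abort("No subjects at risk in this cycle.")
  d <- km_events_in(curve, (cycle - 1) * u, cycle * u)
  c(shape1 = d + 0.5, shape2 = n - d + 0.5)
}
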