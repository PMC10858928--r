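#' Tidy a deterministic comparison into a results table
#'
#' @param x A `cea_result`.
#' @param ... Unused.
#' @return A tibble with one row per reported quantity (per-arm mean
#'   survival, QALYs and cost; differences; INMB) mirroring the layout of
#'   a standard cost-effectiveness results table.
#' @export
tidy.cea_result <- function(x, ...) {
  lab <- sprintf("INMB, € (€%s/%s)",
                 format(x$wtp, big.mark = ","), toupper(x$effect))
  tibble(
    quantity = c("Mean survival time (years)", "Mean QALYs (years)",
                 "Mean cost per patient, €", lab),
    intervention = c(x$intervention$ly, x$intervention$qaly,
                     x$intervention$cost, NA),
    control = c(x$control$ly, x$control$qaly, x$control$cost, NA),
    difference = c(x$delta_ly, x$delta_qaly, x$delta_c, x$inmb)
  )
}

#' @export
glance.cea_result <- function(x, ...) {
  tibble(delta_e = x$delta_e, delta_c = x$delta_c, inmb = x$inmb,
         icer = x$icer, dominance = x$dominance, wtp = x$wtp,
         effect = x$effect)
}

#' Tidy PSA results
#'
#' @param x A `psa_result`.
#' @param type `"summary"` (mean and 95% percentile CI per quantity),
#'   `"draws"` (the simulation table) or `"ceac"` (the acceptability
#'   curve).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.psa_result <- function(x, type = c("summary", "draws", "ceac"), ...) {
  switch(match.arg(type), summary = x$summary, draws = x$draws,
         ceac = x$ceac)
}

#' @export
glance.psa_result <- function(x, ...) {
  s <- setNames(split(x$summary, x$summary$quantity), NULL)
  get <- function(q, col) {
    x$summary[[col]][x$summary$quantity == q]
  }
  tibble(
    delta_e = get("delta_e", "mean"),
    delta_e_lower = get("delta_e", "lower"),
    delta_e_upper = get("delta_e", "upper"),
    delta_c = get("delta_c", "mean"),
    delta_c_lower = get("delta_c", "lower"),
    delta_c_upper = get("delta_c", "upper"),
    inmb = get("inmb", "mean"),
    prob_cost_effective = prob_cost_effective(x),
    n_sims = x$n_sims, n_skipped = x$n_skipped, wtp = x$wtp,
    effect = x$effect
  )
}

#' Tidy a full analysis into a results table with PSA intervals
#'
#' @param x A `cea_analysis`.
#' @param ... Unused.
#' @return The deterministic results table; when a PSA is present, per-arm
#'   and incremental 95% percentile intervals and the probability of
#'   cost-effectiveness at the reference willingness-to-pay are appended.
#' @export
tidy.cea_analysis <- function(x, ...) {
  out <- tidy(x$deterministic)
  if (is.null(x$psa)) return(out)
  s <- x$psa$summary
  ci <- function(q) {
    row <- s[s$quantity == q, ]
    sprintf("[%.3g; %.3g]", row$lower, row$upper)
  }
  out$psa_ci_difference <- c(
    if (x$effect == "ly") ci("delta_e") else NA_character_,
    if (x$effect == "qaly") ci("delta_e") else NA_character_,
    ci("delta_c"), ci("inmb"))
  out <- bind_rows(out, tibble(
    quantity = sprintf("Cost-effectiveness probability (€%s/%s)",
                       format(x$wtp %||% x$params$wtp, big.mark = ","),
                       toupper(x$effect)),
    difference = prob_cost_effective(x$psa)
  ))
  out
}

#' @export
glance.cea_analysis <- function(x, ...) {
  g <- glance(x$deterministic)
  g$analysis <- x$analysis
  if (!is.null(x$psa)) {
    g$psa_inmb <- glance(x$psa)$inmb
    g$prob_cost_effective <- prob_cost_effective(x$psa)
  }
  g
}
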