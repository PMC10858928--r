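#' Plot a cohort trace as stacked state occupancy
#'
#' @param object A `cohort_trace`.
#' @param ... Unused.
#' @return A ggplot: occupancy by cycle, filled by health state.
#' @export
autoplot.cohort_trace <- function(object, ...) {
  dat <- state_occupancy(object) |>
    mutate(state = factor(.data$state, levels = c("dead", "cured",
                                                  "post_event",
                                                  "event_free")))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$cycle, y = .data$occupancy,
                                    fill = .data$state)) +
    ggplot2::geom_area() +
    ggplot2::labs(x = "Cycle (months)", y = "State occupancy",
                  fill = "State",
                  title = sprintf("Cohort trace (%s arm)",
                                  attr(object, "arm"))) +
    ggplot2::theme_minimal()
}

#' Plot the cost-effectiveness acceptability curve
#'
#' @param object A `psa_result`.
#' @param ... Unused.
#' @return A ggplot of P(cost-effective) against willingness-to-pay.
#' @export
autoplot.psa_result <- function(object, ...) {
  ggplot2::ggplot(object$ceac,
                  ggplot2::aes(x = .data$wtp,
                               y = .data$prob_cost_effective)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$wtp, linetype = "dashed") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = sprintf("Willingness-to-pay (€ per %s)",
                              toupper(object$effect)),
                  y = "Probability cost-effective",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
}

#' Incremental cost-effectiveness scatter plot
#'
#' One point per PSA draw on the incremental cost-effectiveness plane,
#' with the willingness-to-pay threshold line through the origin.
#'
#' @param psa A `psa_result`.
#' @param wtp Willingness-to-pay for the threshold line; defaults to the
#'   PSA's reference value.
#' @return A ggplot.
#' @export
plot_ce_plane <- function(psa, wtp = psa$wtp) {
  ggplot2::ggplot(psa$draws, ggplot2::aes(x = .data$delta_e,
                                          y = .data$delta_c)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.6) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey40") +
    ggplot2::geom_abline(slope = wtp, intercept = 0,
                         linetype = "dashed") +
    ggplot2::labs(x = sprintf("Incremental effect (%s)",
                              toupper(psa$effect)),
                  y = "Incremental cost (€)",
                  title = "Incremental cost-effectiveness plane") +
    ggplot2::theme_minimal()
}

#' Tornado diagram of the one-way sensitivity analysis
#'
#' @param object A `tornado_result`.
#' @param ... Unused.
#' @return A ggplot: horizontal bars spanning the INMB at each parameter's
#'   lower and upper bound, widest at the top, with the base-case INMB as
#'   a vertical line.
#' @export
autoplot.tornado_result <- function(object, ...) {
  dat <- object |>
    mutate(parameter = factor(.data$parameter,
                              levels = rev(.data$parameter)))
  ggplot2::ggplot(dat, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$inmb_low,
                                       xend = .data$inmb_high,
                                       yend = .data$parameter),
                          linewidth = 4, colour = "grey55") +
    ggplot2::geom_vline(xintercept = object$inmb_base[1],
                        linetype = "dashed") +
    ggplot2::labs(x = "INMB (€)", y = NULL,
                  title = "One-way sensitivity analysis") +
    ggplot2::theme_minimal()
}
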