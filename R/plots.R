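#' Plot a cohort trace as stacked state occupancy
#'
#' @param object A `psm_trace`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.psm_trace <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object), c("pfs", "pd", "dead"),
                            names_to = "state", values_to = "occupancy")
  df$state <- factor(df$state, levels = c("dead", "pd", "pfs"),
                     labels = c("Dead", "Progressed disease", "Progression-free"))
  ggplot2::ggplot(df, ggplot2::aes(.data$time_years, .data$occupancy,
                                   fill = .data$state)) +
    ggplot2::geom_area(alpha = 0.85) +
    ggplot2::labs(x = "Time (years)", y = "State occupancy", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Tornado diagram of one-way sensitivity results
#'
#' @param object A `psm_tornado` from [one_way()].
#' @param top Show only the `top` widest parameters.
#' @param ... Unused.
#' @return A ggplot; the dashed line marks the base-case ICER.
#' @export
autoplot.psm_tornado <- function(object, top = 12, ...) {
  base_icer <- attr(object, "icer_base")
  df <- utils::head(as_tibble(object), top)
  df$parameter <- factor(df$parameter, levels = rev(df$parameter))
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$icer_at_low,
                                       xend = .data$icer_at_high,
                                       y = .data$parameter,
                                       yend = .data$parameter),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = base_icer, linetype = "dashed") +
    ggplot2::labs(x = "ICER ($/QALY)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness acceptability curve plot
#'
#' @param object A `psm_ceac` tibble from [ceac()].
#' @param wtp Optional WTP threshold to mark.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.psm_ceac <- function(object, wtp = NULL, ...) {
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(.data$wtp, .data$prob_cost_effective)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay ($/QALY)",
                  y = "P(cost-effective)") +
    ggplot2::theme_minimal()
  if (!is.null(wtp)) p <- p + ggplot2::geom_vline(xintercept = wtp, linetype = "dashed")
  p
}

#' Incremental cost-effectiveness plane from PSA draws
#'
#' @param object A `psm_psa`.
#' @param ... Unused.
#' @return A ggplot of the (dQALY, dCost) cloud with the WTP line.
#' @export
autoplot.psm_psa <- function(object, ...) {
  ggplot2::ggplot(object$samples,
                  ggplot2::aes(.data$delta_qaly, .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8, colour = "steelblue") +
    ggplot2::geom_abline(slope = object$wtp, intercept = 0, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.2) +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost ($)") +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier overlay of IPD against a digitized curve or fitted model
#'
#' @param ipd Tibble `time_months`, `event`.
#' @param curve Optional digitized curve tibble to overlay.
#' @param fit Optional `psm_fit`/`dist_spec` to overlay.
#' @return A ggplot.
#' @export
plot_km <- function(ipd, curve = NULL, fit = NULL) {
  km <- km_estimate(ipd)
  p <- ggplot2::ggplot(km, ggplot2::aes(.data$time_months, .data$survival)) +
    ggplot2::geom_step(colour = "black") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Survival") +
    ggplot2::theme_minimal()
  if (!is.null(curve)) {
    p <- p + ggplot2::geom_step(data = curve, colour = "firebrick",
                                linetype = "dashed")
  }
  if (!is.null(fit)) {
    tt <- seq(0, max(km$time_months), length.out = 200)
    p <- p + ggplot2::geom_line(
      data = tibble(time_months = tt, survival = survival_at(fit, tt)),
      colour = "steelblue")
  }
  p
}
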