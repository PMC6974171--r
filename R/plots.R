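# ggplot2 figure builders for the main result types.

#' @rdname run_cohort
#' @param object An `ats_outcome`.
#' @export
autoplot.ats_outcome <- function(object, ...) {
  tr <- tidy(object)
  tr$state <- factor(tr$state, levels = PATHWAYS)
  ggplot2::ggplot(
    dplyr::summarise(dplyr::group_by(tr, .data$cycle, .data$state),
                     occupancy = sum(.data$occupancy), .groups = "drop"),
    ggplot2::aes(x = .data$cycle, y = .data$occupancy, fill = .data$state)) +
    ggplot2::geom_area(position = "stack") +
    ggplot2::labs(x = "Cycle (3 months each)", y = "Cohort fraction",
                  fill = "Health state",
                  title = sprintf("Cohort occupancy, %s strategy", object$strategy)) +
    ggplot2::theme_minimal()
}

#' @rdname run_psa
#' @param object An `ats_psa`.
#' @export
autoplot.ats_psa <- function(object, ...) {
  wtp <- min(object$wtp_grid)
  ggplot2::ggplot(object$draws,
                  ggplot2::aes(x = .data$delta_qalys, y = .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.6) +
    ggplot2::geom_abline(slope = wtp, intercept = 0, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "Incremental QALYs (operative - non-operative)",
                  y = "Incremental cost (2014 USD)",
                  title = "Cost-effectiveness plane",
                  subtitle = sprintf("dashed: WTP $%s/QALY", format(wtp, big.mark = ","))) +
    ggplot2::theme_minimal()
}

#' Plot a cost-effectiveness acceptability curve
#'
#' @param psa An `ats_psa` from [run_psa()].
#' @param wtp_grid Willingness-to-pay grid for the curve.
#' @return A ggplot object.
#' @export
plot_ceac <- function(psa, wtp_grid = seq(0, 150000, by = 2500)) {
  cc <- tidyr::pivot_longer(ceac(psa, wtp_grid),
                            cols = c("fraction_nonoperative", "fraction_operative"),
                            names_to = "strategy", values_to = "fraction",
                            names_prefix = "fraction_")
  ggplot2::ggplot(cc, ggplot2::aes(x = .data$wtp, y = .data$fraction,
                                   colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness-to-pay ($/QALY)",
                  y = "Probability cost-effective",
                  colour = "Strategy",
                  title = "Cost-effectiveness acceptability curves") +
    ggplot2::theme_minimal()
}

#' Plot a tornado diagram
#'
#' @param tornado_tbl Ranked tibble from [tornado()].
#' @return A ggplot object.
#' @export
plot_tornado <- function(tornado_tbl) {
  tt <- dplyr::mutate(tornado_tbl,
                      parameter = factor(.data$parameter,
                                         levels = rev(.data$parameter)))
  ggplot2::ggplot(tt) +
    ggplot2::geom_segment(ggplot2::aes(y = .data$parameter, yend = .data$parameter,
                                       x = .data$nmb_difference_low,
                                       xend = .data$nmb_difference_high),
                          linewidth = 4, colour = "grey55") +
    ggplot2::geom_vline(ggplot2::aes(xintercept = .data$nmb_difference_base),
                        linetype = "dashed") +
    ggplot2::labs(x = "NMB difference, operative - non-operative ($)",
                  y = NULL, title = "Tornado diagram") +
    ggplot2::theme_minimal()
}
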