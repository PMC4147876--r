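#' Plot the cost-effectiveness plane
#'
#' Scatter of total cost against total effectiveness per Monte Carlo draw, one
#' point cloud per strategy. The further right a cloud sits, the more
#' satisfaction-years the strategy yields; the further up, the more it costs.
#'
#' @param object An `"od_psa"` tibble from [simulate_psa()].
#' @param max_points Thin the scatter to at most this many draws per strategy
#'   (plotting all 50,000 draws is rarely useful); `Inf` keeps all.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot od_psa
#' @export
autoplot.od_psa <- function(object, max_points = 5000, ...) {
  long <- tidy.od_psa(object)
  if (is.finite(max_points)) {
    long <- dplyr::slice_head(dplyr::group_by(long, .data$strategy),
                              n = as.integer(max_points))
    long <- dplyr::ungroup(long)
  }
  ggplot2::ggplot(long, ggplot2::aes(x = .data$effect, y = .data$cost,
                                     colour = .data$strategy,
                                     shape = .data$strategy)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(six = "#c0392b", four = "#2c6fbb")) +
    ggplot2::labs(x = "Effectiveness (satisfaction-years)", y = "Cost (EUR)",
                  colour = "Implants", shape = "Implants",
                  title = "Cost-effectiveness plane") +
    ggplot2::theme_minimal()
}

#' Plot cost-effectiveness acceptability curves
#'
#' The probability that each strategy is the preferable one (higher net
#' monetary benefit) as a function of the willingness-to-pay per
#' satisfaction-year. The six-implant strategy becomes the more probably
#' preferred option where its curve crosses 0.5.
#'
#' @param object An `"od_ceac"` tibble from [ceac()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot od_ceac
#' @export
autoplot.od_ceac <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("p_six", "p_four"),
                              names_to = "strategy", values_to = "probability",
                              names_prefix = "p_")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$lambda, y = .data$probability,
                                     colour = .data$strategy)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed", colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(six = "#c0392b", four = "#2c6fbb")) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Willingness-to-pay (EUR per satisfaction-year)",
                  y = "Probability of being preferable",
                  colour = "Implants",
                  title = "Cost-effectiveness acceptability curves") +
    ggplot2::theme_minimal()
}

#' Plot a cohort trace
#'
#' Stacked occupancy of the implant-count states over the model cycles for one
#' evaluated strategy.
#'
#' @param object An `"od_cohort"` from [run_cohort()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot od_cohort
#' @export
autoplot.od_cohort <- function(object, ...) {
  long <- tidyr::pivot_longer(object$trace, dplyr::starts_with("p_count_"),
                              names_to = "count", values_to = "probability",
                              names_prefix = "p_count_")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cycle, y = .data$probability,
                                     fill = .data$count)) +
    ggplot2::geom_area(position = "stack") +
    ggplot2::scale_fill_viridis_d(direction = -1) +
    ggplot2::labs(x = "Cycle (year)", y = "State occupancy",
                  fill = "Implants left",
                  title = sprintf("Implant-count occupancy, %s-implant strategy",
                                  object$strategy)) +
    ggplot2::theme_minimal()
}
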