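#' Plot a network trajectory
#'
#' Marker levels over time; transit compartments are hidden by default.
#'
#' @param object A trajectory from [simulate_network()].
#' @param compartments Also draw the chain compartment levels (dotted).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.network_trajectory <- function(object, compartments = FALSE, ...) {
  long <- tidyr::pivot_longer(object, -"time",
                              names_to = "state", values_to = "level")
  if (!compartments) {
    long <- dplyr::filter(long, .data$state %in% marker_names())
  }
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$level,
                                     colour = .data$state)) +
    ggplot2::geom_line(ggplot2::aes(
      linetype = ifelse(.data$state %in% marker_names(), "marker", "compartment"))) +
    ggplot2::scale_linetype_manual(values = c(marker = "solid",
                                              compartment = "dotted"),
                                   guide = "none") +
    ggplot2::labs(x = "time (months)", y = "level",
                  title = "Mini network trajectory") +
    ggplot2::theme_minimal()
}

#' Plot group trajectories of disruption quantities
#'
#' Mean +/- sd of a disruption quantity per group over visit months, the
#' numbers produced by [longitudinal_summary()].
#'
#' @param data Cohort tibble with disruption columns (e.g. the `params`
#'   element of [run_pipeline()]).
#' @param var One of `"pf"`, `"U"`, `"K"`, `"phi"`.
#' @return A ggplot object.
#' @export
plot_longitudinal <- function(data, var = c("pf", "U", "K", "phi")) {
  var <- match.arg(var)
  s <- longitudinal_summary(data)
  m <- paste0(var, "_mean"); e <- paste0(var, "_sd")
  ggplot2::ggplot(s, ggplot2::aes(.data$month, .data[[m]],
                                  colour = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data[[m]] - .data[[e]],
                                      ymax = .data[[m]] + .data[[e]],
                                      fill = .data$group),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "visit month", y = var,
                  title = sprintf("%s by group over visits", var)) +
    ggplot2::theme_minimal()
}

#' Plot marker contributions to disruption
#'
#' Bar chart of the percentage contribution of each evaluated marker subset
#' (see [marker_contributions()]).
#'
#' @param contributions Output of [marker_contributions()].
#' @return A ggplot object.
#' @export
plot_contributions <- function(contributions) {
  ggplot2::ggplot(contributions,
                  ggplot2::aes(stats::reorder(.data$subset,
                                              .data$contribution_pct),
                               .data$contribution_pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "contribution to disruption (%)",
                  title = "Marker contribution to network disruption") +
    ggplot2::theme_minimal()
}
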