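#' Ensemble boxplot panels
#'
#' Draws the across-member distribution of a metric per site and scenario
#' group: box at the 25th/75th percentiles, median line, whiskers at the
#' 10th/90th percentiles, outliers as points.
#'
#' @param ensemble A `wheat_ensemble` from [run_ensemble()].
#' @param metric One of the summarized metrics (e.g. `"mean_yield"`, `"cv"`,
#'   `"wsi_p95"`).
#' @return A ggplot object.
#' @export
plot_ensemble_boxplots <- function(ensemble, metric = "mean_yield") {
  bp <- dplyr::filter(ensemble$boxplots, .data$metric == !!metric)
  if (nrow(bp) == 0) abort(paste0("metric not summarized: ", metric))
  pts <- bp |>
    dplyr::select("site", "group", "outliers") |>
    tidyr::unnest("outliers")
  ggplot2::ggplot(bp, ggplot2::aes(x = .data$group)) +
    ggplot2::geom_boxplot(
      ggplot2::aes(ymin = .data$p10, lower = .data$q25, middle = .data$median,
                   upper = .data$q75, ymax = .data$p90, fill = .data$group),
      stat = "identity", width = 0.6, show.legend = FALSE) +
    ggplot2::geom_point(data = pts, ggplot2::aes(y = .data$outliers),
                        shape = 1, size = 1.5) +
    ggplot2::facet_wrap(~site) +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal()
}

#' Yield-loss versus recurrence-interval plot
#'
#' @param ensemble A `wheat_ensemble`.
#' @return A ggplot object: water-stress loss level against the average
#'   recurrence interval (2, 4, 10, 20 years), one line per site and
#'   scenario group (medians across members).
#' @export
plot_loss_curves <- function(ensemble) {
  groups <- scenario_groups(ensemble$manifest$scenarios)
  lc <- ensemble$loss_curves |>
    dplyr::mutate(group = groups[match(
      .data$scenario, vapply(ensemble$manifest$scenarios, `[[`, "", "label"))]) |>
    dplyr::summarise(wsi_loss = stats::median(.data$wsi_loss),
                     .by = c("site", "group", "recurrence_years"))
  ggplot2::ggplot(lc, ggplot2::aes(.data$recurrence_years, 100 * .data$wsi_loss,
                                   colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = c(2, 4, 10, 20)) +
    ggplot2::facet_wrap(~site) +
    ggplot2::labs(x = "recurrence interval (years)",
                  y = "yield loss from water stress (%)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname run_ensemble
#' @param object A `wheat_ensemble`.
#' @param metric Metric to plot.
#' @method autoplot wheat_ensemble
#' @export
autoplot.wheat_ensemble <- function(object, metric = "mean_yield", ...) {
  plot_ensemble_boxplots(object, metric)
}
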