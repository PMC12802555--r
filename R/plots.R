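# ggplot2 visualisations of DVH curves, cohort Delta-DVH bands, and cohort
# geometry metrics.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a cumulative DVH curve
#'
#' @param object A [compute_dvh()] curve.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dvh_curve <- function(object, ...) {
  df <- tibble::tibble(dose = object$dose_edges, vol = object$rel_volume)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dose, y = .data$vol)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::labs(x = "Dose (cGy)", y = "Relative volume (%)") +
    ggplot2::theme_minimal()
}

#' Plot cohort Delta-DVH percentile bands
#'
#' Shaded central percentile envelopes (widest = outermost level) around the
#' mean Delta-DVH curve, in the style of cohort DVH-difference figures.
#'
#' @param object A [cohort_bands()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cohort_bands <- function(object, ...) {
  b <- object$bands
  p <- ggplot2::ggplot(b, ggplot2::aes(x = .data$dose_cgy))
  n <- length(object$levels)
  for (i in seq_along(object$levels)) {
    L <- object$levels[i]
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data[[sprintf("lo_%g", L)]],
                   ymax = .data[[sprintf("hi_%g", L)]]),
      fill = "darkgreen", alpha = 0.25 + 0.15 * i)
  }
  p + ggplot2::geom_line(ggplot2::aes(y = .data$mean), color = "red",
                         linewidth = 1) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::labs(x = "Dose (cGy)",
                  y = "Δ relative volume (percentage points)") +
    ggplot2::theme_minimal()
}

#' Box plots of cohort geometry metrics by strategy
#'
#' One panel per organ, boxes per strategy, for a chosen image pair and
#' metric.
#'
#' @param report An [run_experiment()] report (or its metrics tibble).
#' @param pair Image-pair tag to show.
#' @param metric One of `"dsc"`, `"dta_mean_cm"`, `"dta_max_cm"`.
#' @return A ggplot object.
#' @export
plot_geometry_metrics <- function(report, pair = "R2B", metric = "dsc") {
  df <- if (inherits(report, "experiment_report")) report$metrics else report
  df <- dplyr::filter(df, .data$pair == !!pair)
  assert_that(nrow(df) > 0, "no rows for pair %s", pair)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$strategy, y = .data[[metric]])) +
    ggplot2::geom_boxplot(outlier.size = 0.8) +
    ggplot2::facet_wrap(~organ, scales = "free_y") +
    ggplot2::labs(x = NULL, y = metric, title = pair) +
    ggplot2::theme_minimal()
}

#' Maximum distance to agreement versus bladder volume change
#'
#' Scatter of bladder DTA_max against the realised bladder fill ratio, by
#' strategy: the diagnostic view of large-deformation registration failure.
#'
#' @param report An [run_experiment()] report (or its metrics tibble).
#' @param pair Image-pair tag to show.
#' @return A ggplot object.
#' @export
plot_dta_vs_fill <- function(report, pair = "R2B") {
  df <- if (inherits(report, "experiment_report")) report$metrics else report
  df <- dplyr::filter(df, .data$pair == !!pair, .data$organ == "bladder")
  assert_that(nrow(df) > 0, "no bladder rows for pair %s", pair)
  ggplot2::ggplot(df, ggplot2::aes(x = 100 * (.data$fill_realized - 1),
                                   y = .data$dta_max_cm,
                                   color = .data$strategy)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Bladder volume change (%)",
                  y = expression(DTA[max] ~ "(cm)")) +
    ggplot2::theme_minimal()
}
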