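# ggplot2 figures for the main result types.

#' Per-sample diversity trajectories
#'
#' Richness (or another per-sample metric) against time, with one line per
#' time series and a smoothed mean per environment — the standard view of
#' secondary succession after a disturbance at day 0.
#'
#' @param div Output of [diversity_table()].
#' @param metric Column to plot (default `richness_q0`).
#' @param log2_scale Show the response on a log2 axis (default `TRUE` for
#'   richness-like metrics).
#' @return A ggplot object.
#' @export
plot_trajectories <- function(div, metric = "richness_q0",
                              log2_scale = TRUE) {
  p <- ggplot2::ggplot(div, ggplot2::aes(x = .data$time_days,
                                         y = .data[[metric]])) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$study_id), alpha = 0.6) +
    ggplot2::geom_line(
      stat = "smooth", method = "lm", formula = y ~ x, se = FALSE,
      ggplot2::aes(group = .data$time_series_id, colour = .data$study_id),
      linewidth = 0.3, alpha = 0.7,
      data = ~ dplyr::filter(.x, .data$time_days >= 0)) +
    ggplot2::facet_wrap(ggplot2::vars(.data$environment)) +
    ggplot2::labs(x = "Time since disturbance (days)", y = metric) +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
  if (log2_scale) p <- p + ggplot2::scale_y_continuous(trans = "log2")
  p
}

#' Dissimilarity pair values over time
#'
#' @param pairs A pair tibble ([dispersion_pairs()] / [turnover_pairs()]).
#' @return A ggplot object.
#' @export
plot_pairs <- function(pairs) {
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$time_days,
                                      y = .data$value)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$study_id), alpha = 0.5) +
    ggplot2::geom_line(
      stat = "smooth", method = "lm", formula = y ~ x, se = FALSE,
      ggplot2::aes(group = .data$time_series_id, colour = .data$study_id),
      linewidth = 0.3, alpha = 0.7,
      data = ~ dplyr::filter(.x, .data$time_days >= 0)) +
    ggplot2::facet_grid(ggplot2::vars(.data$kind),
                        ggplot2::vars(.data$environment)) +
    ggplot2::labs(x = "Time since disturbance (days)",
                  y = "Bray-Curtis dissimilarity") +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
}

#' Forest plot of classified trends
#'
#' @param object An `mrc_trends` tibble from [classify_trends()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mrc_trends
#' @export
autoplot.mrc_trends <- function(object, ...) {
  d <- object[object$scope == "time_series", , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$slope_mean,
                                  y = stats::reorder(.data$id,
                                                     .data$slope_mean),
                                  colour = .data$classification)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high)) +
    ggplot2::scale_colour_manual(values = c(down = "#2166AC",
                                            neutral = "grey55",
                                            up = "#B2182B"),
                                 drop = FALSE) +
    ggplot2::facet_grid(ggplot2::vars(.data$environment), scales = "free_y",
                        space = "free_y") +
    ggplot2::labs(x = "Slope (link scale)", y = NULL,
                  colour = "trend") +
    ggplot2::theme_minimal()
}

#' Immediate richness effect versus turnover slope
#'
#' Pairs each time series' immediate (before-after) richness effect with
#' its temporal turnover slope, both with credible intervals — the view
#' that separates the environment regimes (no richness loss + drift away;
#' richness loss + recovery toward baseline; weak responses).
#'
#' @param object An `mrc_report` containing both the
#'   `immediate_richness` and `turnover` comparisons.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mrc_report
#' @export
autoplot.mrc_report <- function(object, ...) {
  tr <- object$trends
  need <- c("immediate_richness", "turnover")
  if (!all(need %in% tr$comparison)) {
    abort("report must contain the immediate_richness and turnover comparisons")
  }
  sel <- function(cmp, prefix) {
    d <- tr[tr$comparison == cmp & tr$scope == "time_series", ]
    stats::setNames(
      d[, c("id", "environment", "slope_mean", "ci_low", "ci_high")],
      c("id", "environment", paste0(prefix, c("_mean", "_low", "_high"))))
  }
  d <- dplyr::inner_join(sel("immediate_richness", "richness"),
                         sel("turnover", "turnover"),
                         by = c("id", "environment"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$richness_mean,
                                  y = .data$turnover_mean,
                                  colour = .data$environment)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$turnover_low,
                                        ymax = .data$turnover_high),
                           width = 0, alpha = 0.5) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$richness_low,
                                         xmax = .data$richness_high),
                            height = 0, alpha = 0.5) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Immediate richness effect (log scale)",
                  y = "Turnover slope (logit scale per day)",
                  colour = "environment") +
    ggplot2::theme_minimal()
}
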