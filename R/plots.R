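#' Plot mean cadence adaptation per condition
#'
#' Mean +/- SE of the percent cadence adaptation against the tempo shift,
#' with the identity line (perfect tracking of the music tempo) for
#' reference.
#'
#' @param metrics Metric table from [score_cohort()].
#' @return A ggplot object.
#' @export
plot_adaptation <- function(metrics) {
  df <- metrics |>
    group_by(.data$shift_pct) |>
    summarise(mean = mean(.data$adaptation_pct),
              se = sd(.data$adaptation_pct) / sqrt(dplyr::n()),
              .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$shift_pct, y = .data$mean)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$se,
                                        ymax = .data$mean + .data$se),
                           width = 0.1) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Tempo shift (%)", y = "Cadence adaptation (%)",
                  title = "Cadence adaptation by tempo condition",
                  subtitle = "mean ± SE; dashed line = full tempo tracking")
}

#' Plot the entrainment basin
#'
#' Mean +/- SE tempo-entrainment score per condition; conditions flagged
#' significantly different from the 0 % control are highlighted.
#'
#' @param x A `basin_result` from [basin_analysis()], or a metric table
#'   (in which case the analysis is run first).
#' @param ... Passed to [basin_analysis()] when `x` is a metric table.
#' @return A ggplot object.
#' @export
plot_basin <- function(x, ...) {
  if (!inherits(x, "basin_result")) x <- basin_analysis(x, ...)
  df <- tidy(x) |>
    mutate(flagged = !is.na(.data$significant) & .data$significant)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$shift_pct, y = .data$mean)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$se,
                                        ymax = .data$mean + .data$se),
                           width = 0.1) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$flagged), size = 2.5) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black", `TRUE` = "red"),
                                 name = "below control\n(Bonferroni)") +
    ggplot2::labs(x = "Tempo shift (%)", y = "Tempo entrainment (%)",
                  title = "Entrainment basin",
                  subtitle = "mean ± SE per condition")
}

#' @export
#' @method autoplot basin_result
#' @rdname plot_basin
autoplot.basin_result <- function(object, ...) plot_basin(object, ...)

#' Plot a tempo timeline
#'
#' @param timeline A [tempo_timeline()].
#' @param dt Sampling step for drawing (s).
#' @return A ggplot object.
#' @export
plot_timeline <- function(timeline, dt = 0.5) {
  tt <- seq(0, timeline$end, by = dt)
  df <- tibble(t = tt, bpm = bpm_at(timeline, tt))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$bpm)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = timeline$lap_bounds, linetype = "dotted",
                        colour = "grey50") +
    ggplot2::labs(x = "Time (s)", y = "Music tempo (BPM)",
                  title = sprintf("Tempo timeline (shift %+.2f %%)",
                                  timeline$shift_pct))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
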