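#' Plot an activity frequency distribution
#'
#' Bar chart of the percentage of cells per class: the zero class, the
#' underflow class and the geometric-progression fluorescence bins, in
#' increasing order of activity.
#'
#' @param object An `activity_distribution`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot activity_distribution
#' @export
autoplot.activity_distribution <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$label <- factor(df$label, levels = df$label)
  lab <- attr(object, "variant")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$pct,
                                   fill = .data$class)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(zero = "grey40",
                                          underflow = "grey65",
                                          bin = "steelblue")) +
    ggplot2::labs(
      x = expression("Cell-specific activity class (FU " *
                       cell^-1 * h^-1 * ")"),
      y = "Cells (%)",
      title = if (is.na(lab)) NULL else paste("Variant", lab)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot a growth series with dilution events
#'
#' Chlorophyll concentration over time on a log scale; dashed vertical lines
#' mark dilution events. Between dilutions, exponential growth appears as a
#' straight line.
#'
#' @param object A [growth_series()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot growth_series
#' @export
autoplot.growth_series <- function(object, ...) {
  p <- ggplot2::ggplot(object$samples,
                       ggplot2::aes(x = .data$time_days,
                                    y = .data$chl_ug_L)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Time (days)",
                  y = expression("Chlorophyll a (" * mu * "g " * L^-1 * ")")) +
    ggplot2::theme_minimal()
  if (nrow(object$dilutions) > 0) {
    p <- p + ggplot2::geom_vline(
      data = object$dilutions,
      ggplot2::aes(xintercept = .data$time_days),
      linetype = "dashed", color = "grey50"
    )
  }
  p
}

#' Box-and-whisker plot of per-treatment activity summaries
#'
#' Draws the published comparison style: median bar, 25-75% quartile box and
#' 10-90% percentile whiskers per treatment, from the output of
#' [summarize_activity()].
#'
#' @param summary_tbl Output of [summarize_activity()] grouped by a variant
#'   column.
#' @param group Bare name of the grouping column (default `variant`).
#' @param scale `"FU"` or `"fmol"`.
#' @return A ggplot.
#' @export
plot_activity_summary <- function(summary_tbl, group = variant,
                                  scale = c("FU", "fmol")) {
  scale <- match.arg(scale)
  g <- rlang::ensym(group)
  sfx <- if (scale == "FU") "_FU" else "_fmol"
  cols <- paste0(c("median", "q25", "q75", "p10", "p90"), sfx)
  stopifnot(all(cols %in% names(summary_tbl)))
  ggplot2::ggplot(summary_tbl, ggplot2::aes(x = !!g)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data[[cols[4]]], ymax = .data[[cols[5]]]),
      width = 0.2
    ) +
    ggplot2::geom_crossbar(
      ggplot2::aes(y = .data[[cols[1]]], ymin = .data[[cols[2]]],
                   ymax = .data[[cols[3]]]),
      fill = "white", width = 0.5
    ) +
    ggplot2::labs(
      x = NULL,
      y = if (scale == "FU") {
        expression("Phosphatase activity (FU " * cell^-1 * h^-1 * ")")
      } else {
        expression("Phosphatase activity (fmol " * cell^-1 * h^-1 * ")")
      }
    ) +
    ggplot2::theme_minimal()
}
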