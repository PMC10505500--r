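#' Plot chemical metrics against a sample variable
#'
#' One facet per metric with a shared x axis, so trends of several
#' metrics across a gradient (time, depth, salinity, ...) can be compared
#' at a glance. The returned ggplot carries the plotted data unchanged,
#' so coordinates can be queried programmatically.
#'
#' @param mt Metrics table from [get_metrics()].
#' @param x Name of the x variable (a metadata column or a metric).
#' @param metrics Metric columns to plot; default: all metric columns
#'   present in `mt`.
#' @param color Optional grouping/color column name.
#' @param path Optional output file (png/svg/pdf by extension); written
#'   headlessly with [ggplot2::ggsave()].
#' @return A ggplot object; its facet count equals the number of metrics.
#' @export
plot_metrics <- function(mt, x, metrics = NULL, color = NULL, path = NULL) {
  stopifnot(is.data.frame(mt))
  if (is.null(metrics)) metrics <- intersect(metric_names(), names(mt))
  missing_cols <- setdiff(c(x, metrics, color), names(mt))
  if (length(missing_cols) > 0) {
    stop("column(s) not found in the metrics table: ",
         paste(missing_cols, collapse = ", "))
  }
  if (length(metrics) == 0) stop("no metric columns to plot")
  long <- tidyr::pivot_longer(mt, dplyr::all_of(metrics),
                              names_to = "metric", values_to = "value")
  long$metric <- factor(long$metric, levels = metrics)
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data[[x]], y = .data$value))
  if (!is.null(color)) p <- p + ggplot2::aes(color = .data[[color]])
  p <- p +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = x, y = NULL, color = color)
  if (!is.null(path)) ggplot2::ggsave(path, p)
  p
}

#' Plot two chemical metrics against each other
#'
#' Scatter plot of one metric against another across samples (e.g. nH2O
#' vs Zc), optionally colored and shaped by a grouping variable.
#'
#' @inheritParams plot_metrics
#' @param x_metric,y_metric Metric column names.
#' @param group Optional grouping column mapped to color and shape.
#' @return A ggplot object with one point per sample.
#' @export
plot_metric_pair <- function(mt, x_metric, y_metric, group = NULL,
                             path = NULL) {
  stopifnot(is.data.frame(mt))
  missing_cols <- setdiff(c(x_metric, y_metric, group), names(mt))
  if (length(missing_cols) > 0) {
    stop("column(s) not found in the metrics table: ",
         paste(missing_cols, collapse = ", "))
  }
  p <- ggplot2::ggplot(mt, ggplot2::aes(
    x = .data[[x_metric]], y = .data[[y_metric]]
  )) +
    ggplot2::labs(x = x_metric, y = y_metric)
  if (is.null(group)) {
    p <- p + ggplot2::geom_point()
  } else {
    p <- p + ggplot2::geom_point(ggplot2::aes(
      color = .data[[group]], shape = .data[[group]]
    )) + ggplot2::labs(color = group, shape = group)
  }
  if (!is.null(path)) ggplot2::ggsave(path, p)
  p
}
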