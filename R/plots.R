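# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a conflict time series
#'
#' Fight size against start time, one panel per observation period --
#' the raw view of conflict dynamics over a day.
#'
#' @param object A [conflict_series].
#' @param periods Optional subset of period ids to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.conflict_series <- function(object, periods = NULL, ...) {
  df <- tibble::tibble(
    period_id = object$period_id,
    start_h = object$start_s / 3600,
    size = fight_sizes(object)
  )
  if (!is.null(periods)) df <- df[df$period_id %in% periods, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$start_h, y = .data$size)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$start_h, yend = 0), linewidth = 0.3) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~period_id, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "time within period (h)", y = "fight size") +
    ggplot2::theme_minimal()
}

#' Heatmap of a strategy matrix
#'
#' @param object A `strategy_matrix`.
#' @param ... Unused.
#' @return A ggplot object (tiles, diverging fill: red join, blue avoid).
#' @export
autoplot.strategy_matrix <- function(object, ...) {
  df <- tidy(object, all = TRUE)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$target, y = .data$source, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white", high = "firebrick") +
    ggplot2::labs(
      title = sprintf("(%d,%d)+%s strategy", object$n, object$k, object$combinator),
      x = "target", y = "source", fill = "entry"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text = ggplot2::element_blank(),
      axis.ticks = ggplot2::element_blank()
    )
}

#' Box plots of cost by fight-size class
#'
#' Per-individual aggression frequencies by size class: box, 1.5 IQR
#' whiskers, outliers as points -- the population-cost view of large fights.
#'
#' @param object A `cost_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cost_table <- function(object, ...) {
  kind <- attr(object, "kind")
  ggplot2::ggplot(
    tibble::as_tibble(object),
    ggplot2::aes(x = .data$class, y = .data$frequency)
  ) +
    ggplot2::geom_boxplot(coef = 1.5, outlier.size = 0.8) +
    ggplot2::labs(
      x = "fight-size class",
      y = sprintf("mean frequency of %s aggression received", kind)
    ) +
    ggplot2::theme_minimal()
}

#' Compare long-fraction distributions
#'
#' Overlays the long fraction (share of each fight size among fights larger
#' than two) of several series -- the standard picture for judging which
#' strategy regime a simulation falls into.
#'
#' @param series_list Named list of [conflict_series].
#' @return A ggplot object (log-scaled y).
#' @export
plot_long_fraction <- function(series_list) {
  df <- purrr::map_dfr(names(series_list), function(nm) {
    lf <- long_fraction(series_list[[nm]])
    if (nrow(lf) == 0L) return(tibble::tibble())
    lf$model <- nm
    lf
  })
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$size, y = .data$fraction,
    colour = .data$model, group = .data$model
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "fight size", y = "long fraction") +
    ggplot2::theme_minimal()
}
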