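#' Plot cumulative or deconvolved secretion traces
#'
#' Line plot of per-well traces over time, faceted by channel, with wells
#' colored by class when a calls table is supplied.
#'
#' @param traces Tibble with `well_id`, `channel`, a time column and a value
#'   column (`css` or `dss`).
#' @param value Name of the value column (default the first of `css`, `dss`
#'   present).
#' @param calls Optional `qlcis_calls` tibble; adds class coloring.
#' @param alpha Line transparency.
#' @return A ggplot object.
#' @export
plot_traces <- function(traces, value = NULL, calls = NULL, alpha = 0.4) {
  if (is.null(value)) value <- intersect(c("css", "dss"), names(traces))[1]
  if (is.na(value)) abort("no css/dss column found")
  if (!is.null(calls)) {
    traces <- dplyr::left_join(
      traces, dplyr::distinct(calls, .data$well_id, .data$class),
      by = "well_id")
  }
  time_col <- if ("time" %in% names(traces)) "time" else
    intersect(c("frame", "bin"), names(traces))[1]
  p <- ggplot2::ggplot(traces, ggplot2::aes(
    x = .data[[time_col]], y = .data[[value]],
    group = interaction(.data$well_id, .data$channel)))
  p <- if (!is.null(calls)) {
    p + ggplot2::geom_line(ggplot2::aes(color = .data$class), alpha = alpha)
  } else {
    p + ggplot2::geom_line(alpha = alpha)
  }
  p + ggplot2::facet_wrap(ggplot2::vars(.data$channel)) +
    ggplot2::labs(x = time_col, y = value) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.qlcis_activation <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time,
                                       y = .data$fraction_active)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time since stimulation",
                  y = "fraction of wells activated") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.qlcis_calls <- function(object, ...) {
  per_well <- object |>
    dplyr::group_by(.data$well_id) |>
    dplyr::summarise(max_css = max(.data$max_css), class = .data$class[1],
                     .groups = "drop")
  ggplot2::ggplot(per_well,
                  ggplot2::aes(x = .data$class, y = pmax(.data$max_css, 1e-12))) +
    ggplot2::geom_jitter(width = 0.2, alpha = 0.5) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "activity class", y = "max CSS (log scale)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.qlcis_displacement <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$height, y = .data$distance)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "spot peak height", y = "spot-to-cell distance (um)") +
    ggplot2::theme_minimal()
}
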