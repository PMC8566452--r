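#' Plot the passage metric time series
#'
#' Cell length, area strain and the leading/trailing edge trajectories
#' against time, with the taper, entry and exit planes marked.
#'
#' @param x a `passage_result`
#' @param ... unused
#' @return a ggplot object
#' @method autoplot passage_result
#' @export
autoplot.passage_result <- function(x, ...) {
  s <- x$series
  long <- rbind(
    data.frame(t = s$t_us, value = s$length_um, metric = "cell length (um)"),
    data.frame(t = s$t_us, value = s$area_strain, metric = "area strain"),
    data.frame(t = s$t_us, value = s$lead_x_um, metric = "edges x (um)"),
    data.frame(t = s$t_us, value = s$trail_x_um, metric = "edges x (um)"))
  ggplot2::ggplot(long, ggplot2::aes(.data$t, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (us)", y = NULL,
                  title = sprintf("passage at %g uL/h", x$flow_rate))
}

#' @rdname autoplot.passage_result
#' @export
plot_passage <- function(x, ...) autoplot.passage_result(x, ...)

#' Plot the GA error history
#'
#' Best error per iteration (non-increasing under elitism), on a log
#' scale when the errors span decades.
#'
#' @param x a `ga_result`
#' @param ... unused
#' @return a ggplot object
#' @method autoplot ga_result
#' @export
autoplot.ga_result <- function(x, ...) {
  h <- x$history
  p <- ggplot2::ggplot(h, ggplot2::aes(.data$iteration, .data$best_error)) +
    ggplot2::geom_step() + ggplot2::geom_point() +
    ggplot2::labs(x = "iteration", y = "best error")
  if (all(h$best_error > 0) &&
      max(h$best_error) / min(h$best_error) > 50) p <- p + ggplot2::scale_y_log10()
  p
}

#' @rdname autoplot.ga_result
#' @export
plot_ga_history <- function(x, ...) autoplot.ga_result(x, ...)

#' @importFrom ggplot2 autoplot .data
#' @export
ggplot2::autoplot
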