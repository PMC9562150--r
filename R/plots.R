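#' Plot an influence trajectory
#'
#' Vulnerable fraction and spatial clustering against simulation step.
#'
#' @param object A `vh_trajectory` from [run_influence()] or friends.
#' @param ... Unused.
#' @returns A ggplot object.
#' @export
autoplot.vh_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$steps, c("vulnerable_fraction", "r"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$step, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(x = "step", y = NULL,
                  title = paste0("Influence run (", object$stop_reason, ")")) +
    ggplot2::theme_minimal()
}

#' Plot experiment summaries
#'
#' Cell means with one-standard-error ribbons for a chosen outcome, against
#' the first grid variable, coloured by the second (when present).
#'
#' @param object A results tibble from [run_experiment()].
#' @param metric Outcome column to plot; defaults to `"r"` when present,
#'   otherwise the first metric.
#' @param ... Unused.
#' @returns A ggplot object.
#' @export
plot_experiment <- function(object, metric = NULL, ...) {
  summ <- summarize_experiment(object)
  metric <- metric %||% (if ("r" %in% summ$metric) "r" else summ$metric[1])
  summ <- summ[summ$metric == metric, , drop = FALSE]
  gv <- attr(object, "grid_vars", exact = TRUE)
  xvar <- gv[1]
  colour <- if (length(gv) > 1) gv[2] else NULL
  aes <- if (is.null(colour)) {
    ggplot2::aes(x = .data[[xvar]], y = .data$mean)
  } else {
    ggplot2::aes(x = .data[[xvar]], y = .data$mean,
                 colour = factor(.data[[colour]]), group = factor(.data[[colour]]))
  }
  p <- ggplot2::ggplot(summ, aes) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean - .data$se, ymax = .data$mean + .data$se
    ), fatten = 1.5) +
    ggplot2::labs(x = xvar, y = metric, colour = colour) +
    ggplot2::theme_minimal()
  p
}
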