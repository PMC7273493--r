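#' Plot a log-variance series
#'
#' Line plot of the detection feature over time, with an optional horizontal
#' threshold line.
#'
#' @param object A `logvar_series` from [log_variance()].
#' @param threshold Optional threshold (log-variance units) to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.logvar_series <- function(object, threshold = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$logvar)) +
    ggplot2::geom_line(linewidth = 0.25, colour = "grey30") +
    ggplot2::labs(x = "Time (s)", y = "log-variance") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold,
                                 colour = "steelblue", linetype = "dashed")
  }
  p
}

#' Plot a detection result
#'
#' Log-variance trace with the per-record threshold, detected breaths shaded
#' along the top band and detected apneas shaded full-height.
#'
#' @param object An `apnea_detection` from [detect_record()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.apnea_detection <- function(object, ...) {
  ymax <- max(object$series$logvar)
  ymin <- min(object$series$logvar)
  p <- autoplot(object$series, threshold = object$threshold)
  if (nrow(object$apneas) > 0) {
    p <- p + ggplot2::geom_rect(
      data = object$apneas, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$onset_s, xmax = .data$offset_s,
                   ymin = -Inf, ymax = Inf),
      fill = "firebrick", alpha = 0.15
    )
  }
  if (nrow(object$breaths) > 0) {
    p <- p + ggplot2::geom_rect(
      data = object$breaths, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$onset_s, xmax = .data$offset_s,
                   ymin = ymax + 0.02 * (ymax - ymin),
                   ymax = ymax + 0.08 * (ymax - ymin)),
      fill = "seagreen"
    )
  }
  p
}

#' Bar chart of detection metrics
#'
#' @param metrics An `apnea_metrics` object, or a tibble from
#'   [tidy.apnea_metrics()].
#' @return A ggplot object.
#' @export
plot_metrics <- function(metrics) {
  df <- if (inherits(metrics, "apnea_metrics")) tidy(metrics) else metrics
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue", width = 0.6) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "Value") +
    ggplot2::theme_minimal()
}
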