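#' Plot methods
#'
#' `autoplot()` methods give quick ggplot2 views of each result type: the
#' area-under-curve series and filtered respiration signal (with detected
#' breath peaks), the magnitude spectrum (log scale, respiration band
#' shaded), the cohort scatter of RPM against age by label, and the
#' benchmark accuracy bars.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @name respirad-autoplot
NULL

#' @rdname respirad-autoplot
#' @importFrom ggplot2 autoplot
#' @export
autoplot.auc_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time_s, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "area under curve (amplitude × m)")
}

#' @rdname respirad-autoplot
#' @export
autoplot.respiration_signal <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time_s, .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "time (s)", y = "respiration signal")
}

#' @rdname respirad-autoplot
#' @export
autoplot.rpm_spectrum <- function(object, ...) {
  ggplot2::ggplot(object[-1, ], ggplot2::aes(.data$freq_hz, .data$magnitude)) +
    ggplot2::annotate("rect", xmin = 0, xmax = 0.4, ymin = 0, ymax = Inf,
                      alpha = 0.15, fill = "steelblue") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frequency (Hz)", y = "magnitude",
                  subtitle = "shaded: adult respiration band (< 0.4 Hz)")
}

#' @rdname respirad-autoplot
#' @export
autoplot.rpm_extraction <- function(object, ...) {
  sig <- object$respiration
  pk <- object$result$peak_index
  ggplot2::ggplot(sig, ggplot2::aes(.data$time_s, .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(data = sig[pk, , drop = FALSE], colour = "firebrick") +
    ggplot2::labs(x = "time (s)", y = "respiration signal",
                  subtitle = sprintf("%d peaks in %.1f min → RPM %d",
                                     object$result$peak_count,
                                     object$result$duration_min,
                                     object$result$rpm))
}

#' Cohort scatter: respiration rate against age, by state
#'
#' @param data Cohort tibble from [generate_cohort()].
#' @param cut Optional threshold to draw (breaths/min); `NULL` for none.
#' @return A ggplot object.
#' @export
plot_cohort <- function(data, cut = 18.5) {
  data <- check_cohort_frame(data)
  p <- ggplot2::ggplot(data, ggplot2::aes(.data$age, .data$rpm,
                                          colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "age (years)", y = "respiration rate (breaths/min)",
                  colour = NULL)
  if (!is.null(cut)) {
    p <- p + ggplot2::geom_hline(yintercept = cut, linetype = "dashed")
  }
  p
}

#' @rdname respirad-autoplot
#' @export
autoplot.drowsy_benchmark <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(stats::reorder(.data$model,
                                                      .data$accuracy),
                                       .data$accuracy)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "test accuracy (%)")
}
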