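#' Control-chart plots for a monitor report
#'
#' `type = "daily"` draws the daily-mean metric with centre line and control
#' limits, marking 3σ flags; `type = "cusum"` draws the high-/low-side CUSUM
#' signals with the ±h thresholds and alarm days; `type = "images"` draws the
#' per-image metric chart.
#'
#' @param object A [monitor_stream()] report.
#' @param type `"daily"`, `"cusum"` or `"images"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.monitor_report <- function(object,
                                    type = c("daily", "cusum", "images"),
                                    ...) {
  type <- match.arg(type)
  if (type == "cusum") {
    h <- object$config$h
    df <- object$daily
    long <- tidyr::pivot_longer(
      df[c("day", "s_plus", "s_minus")], cols = c("s_plus", "s_minus"),
      names_to = "side", values_to = "value")
    p <- ggplot2::ggplot(long, ggplot2::aes(.data$day, .data$value,
                                            colour = .data$side)) +
      ggplot2::geom_line() +
      ggplot2::geom_hline(yintercept = c(h, -h), linetype = "dashed") +
      ggplot2::geom_point(data = df[df$alarm, ],
                          ggplot2::aes(.data$day, 0), colour = "black",
                          inherit.aes = FALSE) +
      ggplot2::labs(x = "day", y = "CUSUM signal", colour = NULL,
                    title = sprintf("CUSUM (k = %.3g, h = %.3g)",
                                    object$config$k, h))
    return(p)
  }
  if (type == "daily") {
    df <- object$daily
    lim <- object$daily_limits
    ggplot2::ggplot(df, ggplot2::aes(.data$day, .data$daily_mean)) +
      ggplot2::geom_line() +
      ggplot2::geom_point(ggplot2::aes(colour = .data$flagged)) +
      ggplot2::geom_hline(yintercept = lim$center) +
      ggplot2::geom_hline(yintercept = c(lim$lower, lim$upper),
                          linetype = "dashed") +
      ggplot2::labs(x = "day", y = "daily mean metric",
                    colour = "3σ flag")
  } else {
    df <- object$per_image
    lim <- object$image_limits
    df$index <- seq_len(nrow(df))
    ggplot2::ggplot(df, ggplot2::aes(.data$index, .data$metric,
                                     colour = .data$flagged)) +
      ggplot2::geom_point(size = 0.4) +
      ggplot2::geom_hline(yintercept = lim$center) +
      ggplot2::geom_hline(yintercept = c(lim$lower, lim$upper),
                          linetype = "dashed") +
      ggplot2::labs(x = "image", y = "OOD metric", colour = "3σ flag")
  }
}

#' @rdname autoplot.monitor_report
#' @export
plot_control_chart <- function(object, type = "daily", ...) {
  autoplot.monitor_report(object, type = type, ...)
}

#' @export
autoplot.cusum_run <- function(object, ...) {
  p <- attr(object, "params")
  df <- tibble::as_tibble(object)
  long <- tidyr::pivot_longer(df[c("step", "s_plus", "s_minus")],
                              cols = c("s_plus", "s_minus"),
                              names_to = "side", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$step, .data$value,
                                     colour = .data$side)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = c(p$h, -p$h), linetype = "dashed") +
    ggplot2::labs(x = "step", y = "CUSUM signal", colour = NULL)
}
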