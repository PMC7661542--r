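# ggplot2 visualisations for traces, mass series and fitted profiles.

#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_segment labs
#'   geom_vline theme_minimal
NULL

thin_trace <- function(trace, max_points = 2e5) {
  n <- nrow(trace)
  if (n <= max_points) return(trace)
  trace[seq(1L, n, by = ceiling(n / max_points)), , drop = FALSE]
}

#' Plot a resonance-frequency trace
#'
#' Line plot of resonance frequency against time; traces longer than
#' `max_points` samples are thinned for display only.
#'
#' @param object A `frequency_trace` tibble.
#' @param max_points Display thinning limit.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.frequency_trace <- function(object, max_points = 2e5, ...) {
  df <- thin_trace(object, max_points)
  ggplot(df, aes(x = .data$time_s, y = .data$frequency_hz)) +
    geom_line(linewidth = 0.3) +
    labs(x = "Time (s)", y = "Resonance frequency (Hz)") +
    theme_minimal()
}

#' @export
plot.frequency_trace <- function(x, ...) print(autoplot(x, ...))

#' Plot a calibrated buoyant-mass series
#'
#' @param object A `mass_series` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mass_series <- function(object, ...) {
  ggplot(object, aes(x = .data$time_min, y = .data$mass_ug)) +
    geom_point(size = 0.8, alpha = 0.7) +
    labs(x = "Time (min)", y = "Buoyant mass (µg)") +
    theme_minimal()
}

#' @export
plot.mass_series <- function(x, ...) print(autoplot(x, ...))

#' Plot a fitted dissolution profile
#'
#' Measured buoyant masses with the fitted constant-rate segments overlaid
#' and detected abrupt jumps marked by vertical lines.
#'
#' @param object A `dissolution_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dissolution_profile <- function(object, ...) {
  seg <- object$segments
  seg$y_start <- seg$intercept_ug + seg$rate_ug_min * seg$t_start_min
  seg$y_end <- seg$intercept_ug + seg$rate_ug_min * seg$t_end_min
  p <- ggplot(object$series, aes(x = .data$time_min, y = .data$mass_ug)) +
    geom_point(size = 0.8, alpha = 0.5) +
    geom_segment(
      data = seg,
      aes(x = .data$t_start_min, xend = .data$t_end_min,
          y = .data$y_start, yend = .data$y_end),
      colour = "#d95f02", linewidth = 0.9, inherit.aes = FALSE
    ) +
    labs(x = "Time (min)", y = "Buoyant mass (µg)") +
    theme_minimal()
  if (nrow(object$jumps) > 0) {
    p <- p + geom_vline(xintercept = object$jumps$time_min,
                        linetype = "dashed", colour = "#7570b3")
  }
  p
}

#' @export
plot.dissolution_profile <- function(x, ...) print(autoplot(x, ...))
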