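#' Plot a synthetic recording with its scheduled blinks
#'
#' @param object A `blink_recording` from [generate_recording()].
#' @param ... Unused.
#' @return A ggplot: frequency trace with shaded ground-truth blink spans.
#' @method autoplot blink_recording
#' @export
autoplot.blink_recording <- function(object, ...) {
  lab <- object$labels
  spans <- tibble::tibble(
    xmin = lab$onset_s,
    xmax = lab$onset_s + lab$closing_s + lab$hold_s + lab$opening_s
  )
  ggplot2::ggplot(object$series, ggplot2::aes(.data$time_s, .data$frequency_hz)) +
    ggplot2::geom_rect(
      data = spans,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax, ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "steelblue", alpha = 0.2
    ) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(
      x = "time (s)", y = "resonance frequency (Hz)",
      title = "Synthetic capacitive blink recording"
    )
}

#' Plot the training-loss trajectory of a fatigue network
#'
#' @param object A `fatigue_network` from [fit_fatigue_network()].
#' @param ... Unused.
#' @return A ggplot of mean-squared error against iteration (log y).
#' @method autoplot fatigue_network
#' @export
autoplot.fatigue_network <- function(object, ...) {
  df <- tibble::tibble(iteration = seq_along(object$loss), loss = object$loss)
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "iteration", y = "training MSE",
      title = "Fatigue network training loss"
    )
}

#' Plot a band-pass magnitude response
#'
#' Single-pass response of the second-order-section design on a log-log
#' grid, with the passband shaded.
#'
#' @param spec A [filter_spec()].
#' @param fs Sampling rate in Hz.
#' @param f Frequency grid in Hz (default log-spaced over
#'   `[0.05, fs / 2)`).
#' @return A ggplot of gain in dB versus frequency.
#' @export
plot_filter_response <- function(spec = filter_spec(), fs = 100, f = NULL) {
  stopifnot(inherits(spec, "filter_spec"))
  f <- f %||% exp(seq(log(0.05), log(fs / 2 * 0.999), length.out = 400))
  sos <- butter_bandpass_sos(spec$order, spec$band[1], spec$band[2], fs)
  df <- tibble::tibble(f = f, gain_db = 20 * log10(pmax(sos_response(sos, f, fs), 1e-300)))
  ggplot2::ggplot(df, ggplot2::aes(.data$f, .data$gain_db)) +
    ggplot2::annotate("rect",
      xmin = spec$band[1], xmax = spec$band[2],
      ymin = -Inf, ymax = Inf, fill = "pink", alpha = 0.4
    ) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::coord_cartesian(ylim = c(-120, 5)) +
    ggplot2::labs(
      x = "frequency (Hz)", y = "gain (dB)",
      title = sprintf(
        "Butterworth band-pass, order %d, [%g, %g] Hz",
        spec$order, spec$band[1], spec$band[2]
      )
    )
}

#' Plot detected blink events over the derivative trace
#'
#' @param deriv Tibble from [differentiate()].
#' @param events Tibble from [detect_blinks()].
#' @param threshold Detection threshold to draw (default 4).
#' @return A ggplot of the rescaled derivative with threshold lines and
#'   event onsets.
#' @export
plot_detection <- function(deriv, events, threshold = 4) {
  ggplot2::ggplot(deriv, ggplot2::aes(.data$time_s, .data$deriv)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = c(-threshold, threshold), linetype = 2, colour = "red") +
    ggplot2::geom_vline(
      xintercept = events$onset_s, colour = "steelblue",
      alpha = 0.6
    ) +
    ggplot2::labs(
      x = "time (s)", y = "derivative (robust scales)",
      title = "Blink detection"
    )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
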