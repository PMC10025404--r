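# ggplot2 autoplot() methods for the main result types.

#' Plot a spectrogram
#' @param object an [spectrogram()] result.
#' @param trans power transform for the fill scale, default `log10`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.eeg_spectrogram <- function(object, trans = "log10", ...) {
  df <- tidyr::expand_grid(freq = object$freqs, time = object$times)
  df$power <- as.vector(object$power)
  ggplot2::ggplot(df, ggplot2::aes(.data$time / 60, .data$freq,
                                   fill = .data$power)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(trans = trans, name = "power\n(uV^2/Hz)") +
    ggplot2::labs(x = "time (min)", y = "frequency (Hz)") +
    ggplot2::theme_minimal()
}

#' Plot a band-power series
#' @param object a [band_power()] series.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.band_power_series <- function(object, ...) {
  band <- attr(object, "band"); kind <- attr(object, "kind")
  ggplot2::ggplot(object, ggplot2::aes(.data$time / 60, .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(
      x = "time (min)",
      y = if (identical(kind, "relative")) "relative power (%)" else "power (uV^2)",
      title = sprintf("%.1f-%g Hz band", band[1], band[2])) +
    ggplot2::theme_minimal()
}

#' Plot a peak-frequency track
#' @param object a [peak_frequency()] track.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.freq_track <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time / 60, .data$value)) +
    ggplot2::geom_line(na.rm = TRUE, colour = "grey30") +
    ggplot2::geom_point(size = 0.3, na.rm = TRUE, colour = "grey30") +
    ggplot2::labs(x = "time (min)", y = "peak frequency (Hz)") +
    ggplot2::theme_minimal()
}

#' Plot a sigmoid fit over its data
#' @param object a [fit_sigmoid()] result.
#' @param lambda crossing fraction drawn as a vertical marker.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.sigmoid_fit <- function(object, lambda = 0.05, ...) {
  d <- object$data
  tt <- seq(min(d$time), max(d$time), length.out = 400)
  curve <- tibble(time = tt, value = predict(object, tt))
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$time / 60, .data$value)) +
    ggplot2::geom_point(size = 0.5, alpha = 0.5) +
    ggplot2::geom_line(data = curve, colour = "firebrick") +
    ggplot2::labs(x = "time (min)", y = "band power (uV^2)") +
    ggplot2::theme_minimal()
  if (!isTRUE(object$no_transition) && !is.na(object$c))
    p <- p + ggplot2::geom_vline(
      xintercept = threshold_crossing(object, lambda) / 60,
      linetype = "dashed", colour = "firebrick")
  p
}

#' Plot the suppression segmentation
#' @param object a [segment_suppressions()] result.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.suppression_segments <- function(object, ...) {
  iv <- tidy(object)
  ggplot2::ggplot(iv) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$start / 60,
                                    xmax = .data$end / 60,
                                    ymin = 0, ymax = 1, fill = .data$label)) +
    ggplot2::scale_fill_manual(values = c(IES = "black", alphaS = "orange")) +
    ggplot2::xlim(0, object$duration_s / 60) +
    ggplot2::labs(x = "time (min)", y = NULL, fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
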