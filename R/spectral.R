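# Weighted-average short-time spectrogram and band-level descriptors.

#' Weighted-average EEG spectrogram
#'
#' Magnitude-squared short-time Fourier spectra (Hann taper, one-sided power
#' spectral density in microvolts squared per Hz) are computed per channel on
#' a sliding window and combined as a weighted mean that halves the lateral
#' electrodes: `P_av = (0.5 P_F7 + P_Fp1 + P_Fp2 + 0.5 P_F8) / 3`. The FFT is
#' zero-padded to a 0.05 Hz grid so the 0.1 Hz band edge is resolved.
#'
#' @param record an [eeg_record()].
#' @param window_s window length (s), default 20.
#' @param overlap fractional overlap, default 0.75 (5 s time step).
#' @param max_freq highest frequency retained (Hz), default 45.
#' @param freq_res frequency grid step (Hz), default 0.05.
#' @param weights named channel weights; defaults halve F7 and F8.
#'
#' @return Object of class `eeg_spectrogram`: `times` (window centres, s),
#'   `freqs` (Hz), `power` (freq x time, microvolts^2/Hz).
#' @export
spectrogram <- function(record, window_s = 20, overlap = 0.75,
                        max_freq = 45, freq_res = 0.05,
                        weights = c(F7 = 0.5, Fp1 = 1, Fp2 = 1, F8 = 0.5)) {
  fs <- record$fs
  nw <- as.integer(round(window_s * fs))
  if (ncol(record$samples) < nw)
    abort("Record shorter than one spectrogram window.")
  step <- max(1L, as.integer(round(nw * (1 - overlap))))
  nfft <- max(nw, as.integer(round(fs / freq_res)))
  starts <- seq(1L, ncol(record$samples) - nw + 1L, by = step)
  times <- (starts - 1L + nw / 2) / fs
  freqs <- (0:(nfft %/% 2)) * fs / nfft
  keep <- freqs <= max_freq + 1e-9
  freqs <- freqs[keep]

  w <- 0.5 * (1 - cos(2 * pi * seq(0, nw - 1) / nw))  # Hann taper
  scale <- 1 / (fs * sum(w^2))

  wts <- weights[record$channels]
  if (anyNA(wts)) {
    wts <- rep(1, length(record$channels))
    names(wts) <- record$channels
  }
  acc <- matrix(0, nrow = sum(keep), ncol = length(starts))
  for (ch in seq_along(record$channels)) {
    x <- record$samples[ch, ]
    seg <- matrix(0, nrow = nfft, ncol = length(starts))
    for (j in seq_along(starts))
      seg[1:nw, j] <- x[starts[j]:(starts[j] + nw - 1L)] * w
    X <- stats::mvfft(seg)
    psd <- (Mod(X[seq_len(nfft %/% 2 + 1L), , drop = FALSE])^2) * scale
    psd[2:(nfft %/% 2), ] <- 2 * psd[2:(nfft %/% 2), ]  # one-sided
    acc <- acc + wts[ch] * psd[keep, , drop = FALSE]
  }
  power <- acc / sum(wts)
  structure(list(times = times, freqs = freqs, power = power,
                 window_s = window_s, overlap = overlap,
                 weights = wts, fs = fs),
            class = "eeg_spectrogram")
}

#' @export
print.eeg_spectrogram <- function(x, ...) {
  cat(sprintf("<eeg_spectrogram> %d freqs [%.2f, %.2f] Hz x %d windows (%g s, %.0f%% overlap)\n",
              length(x$freqs), min(x$freqs), max(x$freqs), length(x$times),
              x$window_s, 100 * x$overlap))
  invisible(x)
}

# Trapezoidal band integral of a PSD column set, with interpolated band edges.
trapz_band <- function(freqs, power, band) {
  f1 <- band[1]; f2 <- band[2]
  inside <- which(freqs > f1 & freqs < f2)
  grid <- c(f1, freqs[inside], f2)
  vals <- rbind(
    apply_interp(freqs, power, f1),
    power[inside, , drop = FALSE],
    apply_interp(freqs, power, f2)
  )
  dt <- diff(grid)
  colSums((vals[-1, , drop = FALSE] + vals[-nrow(vals), , drop = FALSE]) / 2 * dt)
}

apply_interp <- function(freqs, power, f0) {
  if (f0 <= freqs[1]) return(power[1, , drop = FALSE])
  if (f0 >= freqs[length(freqs)]) return(power[length(freqs), , drop = FALSE])
  i <- findInterval(f0, freqs)
  a <- (f0 - freqs[i]) / (freqs[i + 1] - freqs[i])
  (1 - a) * power[i, , drop = FALSE] + a * power[i + 1, , drop = FALSE]
}

new_band_series <- function(times, values, band, kind) {
  structure(tibble(time = times, value = values),
            band = band, kind = kind,
            class = c("band_power_series", "tbl_df", "tbl", "data.frame"))
}

#' Absolute band power over time
#'
#' Area under the spectrogram over the frequency band (trapezoidal
#' quadrature), one value per spectrogram window.
#'
#' @param spec an [spectrogram()].
#' @param band numeric length-2 band (Hz), inside the frequency grid.
#' @return A tibble (`time`, `value`) of class `band_power_series`;
#'   `value` in microvolts squared.
#' @export
band_power <- function(spec, band) {
  if (band[1] < spec$freqs[1] - 1e-9 || band[2] > spec$freqs[length(spec$freqs)] + 1e-9)
    abort("`band` lies outside the spectrogram frequency grid.")
  new_band_series(spec$times, trapz_band(spec$freqs, spec$power, band),
                  band, "absolute")
}

#' Relative band power over time
#'
#' Percentage of the energy in `band` relative to the `total` band
#' (0.1-45 Hz by default). Times with zero total power are undefined.
#'
#' @inheritParams band_power
#' @param total reference band (Hz).
#' @return A `band_power_series` tibble; `value` in percent.
#' @export
relative_band_power <- function(spec, band, total = c(0.1, 45)) {
  num <- trapz_band(spec$freqs, spec$power, band)
  den <- trapz_band(spec$freqs, spec$power, total)
  v <- ifelse(den > 0, 100 * num / den, NA_real_)
  new_band_series(spec$times, v, band, "relative")
}

#' Mean band power over a time window
#'
#' Discretized mean of a band-power series over the window (undefined samples
#' excluded); the scalar reducer used for the maintenance-phase means.
#'
#' @param series a [band_power()] / [relative_band_power()] series.
#' @param window numeric length-2 time window (s).
#' @return Scalar mean.
#' @export
mean_band_power <- function(series, window) {
  v <- series$value[series$time >= window[1] & series$time <= window[2]]
  mean(v, na.rm = TRUE)
}

new_freq_track <- function(times, values, band, exclusions, smoothed) {
  structure(tibble(time = times, value = values),
            band = band, exclusions = exclusions, smoothed = smoothed,
            class = c("freq_track", "tbl_df", "tbl", "data.frame"))
}

#' Peak-frequency track
#'
#' Frequency of maximal spectrogram power within a band at each time; ties
#' resolve to the lowest frequency. Times inside the exclusion intervals
#' (iso-electric or alpha suppressions) are undefined.
#'
#' @inheritParams band_power
#' @param exclusions interval table (`start`, `end` in s) where the track is
#'   undefined, or `NULL`.
#' @return A tibble (`time`, `value`) of class `freq_track`.
#' @export
peak_frequency <- function(spec, band, exclusions = NULL) {
  sel <- which(spec$freqs >= band[1] - 1e-9 & spec$freqs <= band[2] + 1e-9)
  if (length(sel) == 0) abort("`band` contains no frequency bins.")
  idx <- apply(spec$power[sel, , drop = FALSE], 2, which.max)
  vals <- spec$freqs[sel][idx]
  excl <- as_intervals(exclusions)
  vals[point_in_intervals(spec$times, excl)] <- NA_real_
  new_freq_track(spec$times, vals, band, excl, smoothed = FALSE)
}

#' Gap-aware Savitzky-Golay smoothing of a peak-frequency track
#'
#' Order-1 local polynomial regression in a sliding window (2 min default)
#' evaluated on a regular 5 s grid, fitted only on defined samples; grid
#' points whose window holds fewer than two defined samples, or which fall
#' inside the track's exclusion set, stay undefined. On a gap-free regular
#' grid this coincides with a linear Savitzky-Golay filter; the local-fit
#' form lets the smoother bridge suppression gaps.
#'
#' @param track a [peak_frequency()] track.
#' @param window_s regression window length (s), default 120.
#' @param step_s output grid step (s), default 5.
#' @return A smoothed `freq_track` on the regular grid.
#' @export
sg_smooth <- function(track, window_s = 120, step_s = 5) {
  t_in <- track$time; v_in <- track$value
  grid <- seq(min(t_in), max(t_in), by = step_s)
  half <- window_s / 2
  def <- !is.na(v_in)
  out <- rep(NA_real_, length(grid))
  for (j in seq_along(grid)) {
    sel <- def & abs(t_in - grid[j]) <= half
    k <- sum(sel)
    if (k < 2) next
    tt <- t_in[sel] - grid[j]; vv <- v_in[sel]
    if (abs(max(tt) - min(tt)) < 1e-9) next
    # closed-form order-1 least squares evaluated at the window centre
    mt <- mean(tt); mv <- mean(vv)
    slope <- sum((tt - mt) * (vv - mv)) / sum((tt - mt)^2)
    out[j] <- mv - slope * mt
  }
  excl <- attr(track, "exclusions")
  out[point_in_intervals(grid, excl)] <- NA_real_
  new_freq_track(grid, out, attr(track, "band"), excl, smoothed = TRUE)
}
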