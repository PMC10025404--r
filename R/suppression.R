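# Dual-envelope, dual-threshold segmentation of iso-electric suppressions
# (IES: broadband flat EEG) and alpha suppressions (alphaS: alpha-band
# amplitude collapse with broadband activity preserved).

#' Alpha-band filtered, RMS-normalized signal
#'
#' The channel-averaged signal is band-pass filtered to 8-16 Hz with a
#' zero-phase 4th-order Butterworth filter, then divided by its global
#' root-mean-square so the output has unit RMS.
#'
#' @param record an [eeg_record()].
#' @param band filter pass band (Hz), default `c(8, 16)`.
#' @param order Butterworth order, default 4.
#' @return A tibble (`time`, `value`) of class `signal_track` with unit RMS.
#' @export
alpha_normalize <- function(record, band = c(8, 16), order = 4) {
  fs <- record$fs
  if (fs <= 2 * band[2]) abort("Sampling rate too low for the 8-16 Hz band.")
  x <- channel_average(record)
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  y <- signal::filtfilt(bf, x)
  r <- sqrt(mean(y^2))
  if (r == 0) abort("Filtered signal has zero RMS; cannot normalize.")
  structure(tibble(time = record_times(record), value = y / r),
            fs = fs,
            class = c("signal_track", "tbl_df", "tbl", "data.frame"))
}

as_signal_track <- function(x, fs) {
  structure(tibble(time = (seq_along(x) - 1) / fs, value = x), fs = fs,
            class = c("signal_track", "tbl_df", "tbl", "data.frame"))
}

#' Upper/lower envelopes by extremum interpolation
#'
#' Linear interpolation through the strict local maxima (upper) and minima
#' (lower) of the track, clamped to the first/last extremum at the ends; the
#' envelope width `D(t) = upper - lower` drives the suppression thresholds.
#' A monotone track without interior extrema degenerates to the track itself
#' (width 0). With `min_sep_s > 0`, only extrema that are the signal's
#' maximum (resp. minimum) within `min_sep_s` on either side are kept: small
#' noise wiggles riding on a slow wave then no longer pull the envelope onto
#' the noise, and the width reflects the oscillation amplitude at scales
#' slower than `min_sep_s`.
#'
#' @param track a tibble with `time` and `value` columns.
#' @param min_sep_s minimum time separation between kept extrema (s);
#'   0 keeps every strict local extremum.
#' @return A tibble (`time`, `upper`, `lower`, `width`) of class
#'   `envelope_pair`.
#' @export
envelopes <- function(track, min_sep_s = 0) {
  t <- track$time; x <- track$value
  n <- length(x)
  if (n < 3) abort("Track must hold at least 3 samples.")
  d <- diff(x)
  maxima <- which(d[-length(d)] > 0 & d[-1] < 0) + 1L
  minima <- which(d[-length(d)] < 0 & d[-1] > 0) + 1L
  if (min_sep_s > 0 && n > 3) {
    dt <- median(diff(t))
    k <- max(1L, as.integer(round(min_sep_s / dt)))
    rmax <- roll_extreme(x, k, max)
    rmin <- roll_extreme(x, k, min)
    maxima <- maxima[x[maxima] >= rmax[maxima]]
    minima <- minima[x[minima] <= rmin[minima]]
  }
  if (length(maxima) == 0 || length(minima) == 0) {
    up <- x; lo <- x
  } else {
    up <- approx(t[maxima], x[maxima], xout = t, rule = 2)$y
    lo <- approx(t[minima], x[minima], xout = t, rule = 2)$y
  }
  structure(tibble(time = t, upper = up, lower = lo, width = up - lo),
            class = c("envelope_pair", "tbl_df", "tbl", "data.frame"))
}

# Running extreme over a centred window of +/- k samples (van Herk block
# cummax: O(n), exact). `fun` is max or min.
roll_extreme <- function(x, k, fun = max) {
  n <- length(x)
  w <- 2L * k + 1L
  pad <- if (identical(fun, max)) -Inf else Inf
  nb <- ceiling((n + 2L * k) / w) * w
  xp <- c(rep(pad, k), x, rep(pad, nb - n - k))
  m <- matrix(xp, nrow = w)
  L <- apply(m, 2, if (identical(fun, max)) cummax else cummin)
  R <- apply(m[w:1, , drop = FALSE], 2,
             if (identical(fun, max)) cummax else cummin)[w:1, , drop = FALSE]
  Lv <- as.vector(L); Rv <- as.vector(R)
  i <- k + seq_len(n)   # centre positions in padded coordinates
  lo <- i - k; hi <- i + k
  if (identical(fun, max)) pmax(Rv[lo], Lv[hi]) else pmin(Rv[lo], Lv[hi])
}

#' Segment iso-electric and alpha suppressions
#'
#' Envelope widths of the broadband channel-averaged signal (`D`) and of the
#' normalized alpha-band signal (`D_alpha`) — measured as the running
#' max-minus-min range within the extremum-separation window, which equals
#' the crest-interpolated envelope width on steady oscillations while
#' responding within one window at suppression edges — are thresholded at
#' `T_IES = min(8, median(D))` microvolts and `T_alpha = min(0.25,
#' median(D_alpha))`: samples with `D < T_IES` and `D_alpha < T_alpha` form
#' the IES set, samples with `D > T_IES` and `D_alpha < T_alpha` the alphaS
#' set (thresholding the instantaneous envelope width rather than the raw
#' trace avoids firing at every zero crossing). Each sample set is aggregated
#' into intervals at the sampling step and smoothed by morphological erosion
#' then dilation (opening) with a 0.5 s structuring element. Because the
#' alpha envelope collapses faster than the broadband envelope at a
#' suppression onset, the dual rule produces short alphaS slivers flanking
#' each IES; slivers shorter than `collar_s` that directly abut an IES
#' interval are transition artifacts and are absorbed into it.
#'
#' @param record an [eeg_record()], preprocessed.
#' @param struct_s structuring-element length for the opening (s).
#' @param t_ies_cap,t_alpha_cap caps of the two thresholds.
#' @param broad_sep_s,alpha_sep_s minimum extremum separations for the
#'   broadband and alpha-band envelopes (s); the broadband default 0.6 s
#'   keeps the envelope on the slow-wave crests rather than on noise wiggles.
#' @param collar_s alphaS slivers up to this long abutting an IES are merged
#'   into it (transition collars).
#' @return Object of class `suppression_segments`: interval tibbles `ies` and
#'   `alpha_s`, thresholds `t_ies` (microvolts) and `t_alpha` (unitless), and
#'   whole-record totals `s_ies_total_min`, `l_ies_max_min`.
#' @export
segment_suppressions <- function(record, struct_s = 0.5,
                                 t_ies_cap = 8, t_alpha_cap = 0.25,
                                 broad_sep_s = 0.6, alpha_sep_s = 0.05,
                                 collar_s = 3) {
  fs <- record$fs
  broad <- as_signal_track(channel_average(record), fs)
  # envelope width as the running max-min range within +/- sep: equal to the
  # crest-interpolated width on steady oscillations, but with bounded,
  # symmetric response at suppression onsets (linear interpolation across a
  # step lags by the full inter-crest gap and can overshoot far into the
  # suppression)
  range_width <- function(x, sep_s) {
    k <- max(1L, as.integer(round(sep_s * fs)))
    roll_extreme(x, k, max) - roll_extreme(x, k, min)
  }
  width_b <- range_width(broad$value, broad_sep_s)
  width_a <- range_width(alpha_normalize(record)$value, alpha_sep_s)

  t_ies <- min(t_ies_cap, median(width_b))
  t_alpha <- min(t_alpha_cap, median(width_a))

  low_alpha <- width_a < t_alpha
  cond_ies <- width_b < t_ies & low_alpha
  cond_as <- width_b > t_ies & low_alpha

  k <- max(1L, as.integer(round(struct_s * fs)))
  times <- broad$time
  ies <- intervals_from_mask(morph_open(cond_ies, k), times)
  alpha_s <- intervals_from_mask(morph_open(cond_as, k), times)

  if (collar_s > 0 && nrow(ies) > 0 && nrow(alpha_s) > 0) {
    dt <- 1 / fs
    is_collar <- vapply(seq_len(nrow(alpha_s)), function(i) {
      len <- alpha_s$end[i] - alpha_s$start[i]
      len <= collar_s &&
        any(abs(alpha_s$end[i] - ies$start) <= 2 * dt |
              abs(alpha_s$start[i] - ies$end) <= 2 * dt)
    }, logical(1))
    if (any(is_collar)) {
      ies <- merge_intervals(bind_rows(ies, alpha_s[is_collar, ]))
      alpha_s <- alpha_s[!is_collar, ]
    }
  }

  dur <- interval_durations(ies)
  structure(list(
    ies = ies, alpha_s = alpha_s,
    t_ies = t_ies, t_alpha = t_alpha,
    fs = fs, duration_s = record_duration(record),
    s_ies_total_min = sum(dur) / 60,
    l_ies_max_min = if (length(dur) > 0) max(dur) / 60 else 0
  ), class = "suppression_segments")
}

#' @export
print.suppression_segments <- function(x, ...) {
  cat(sprintf("<suppression_segments> %d IES (%.2f min total), %d alphaS; T_IES=%.2f uV, T_alpha=%.3f\n",
              nrow(x$ies), x$s_ies_total_min, nrow(x$alpha_s),
              x$t_ies, x$t_alpha))
  invisible(x)
}

#' @export
tidy.suppression_segments <- function(x, ...) {
  bind_rows(
    mutate(x$ies, label = "IES"),
    mutate(x$alpha_s, label = "alphaS")
  ) %>% arrange(.data$start)
}

#' Suppression totals over a time window
#'
#' Intervals intersecting the window are clipped to it; the total (`s_ies`)
#' and longest (`l_ies`) clipped durations are returned in minutes.
#'
#' @param segments a [segment_suppressions()] result, or an interval tibble.
#' @param window numeric length-2 time window (s).
#' @param set which interval set to use when `segments` is classed.
#' @return One-row tibble (`s_ies_min`, `l_ies_min`).
#' @export
suppression_stats <- function(segments, window, set = c("ies", "alpha_s")) {
  iv <- if (inherits(segments, "suppression_segments"))
    segments[[match.arg(set)]] else as_intervals(segments)
  cl <- clip_intervals(iv, window)
  dur <- interval_durations(cl)
  tibble(
    s_ies_min = sum(dur) / 60,
    l_ies_min = if (length(dur) > 0) max(dur) / 60 else 0
  )
}
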