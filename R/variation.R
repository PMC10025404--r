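# Total-variation instability statistic of the smoothed peak-frequency
# tracks: the cumulated absolute excursion of the track per unit time
# (Hz/min), summed over the suppression-free segments, zero for a track that
# is flat on every segment.

#' Total variation of a peak-frequency track
#'
#' Within each suppression-free segment the track is discretized at its local
#' extrema (strict sign changes of consecutive differences, first sample of a
#' plateau, plus both segment endpoints); the statistic is the sum over
#' segments of the absolute differences between consecutive extremum values,
#' divided by the summed segment spans in minutes. For a piecewise-monotone
#' track this equals the sum of all consecutive absolute sample differences.
#'
#' @param track a (smoothed) [peak_frequency()] track.
#' @param segments interval table of the spans where the band is present;
#'   default: complement of the track's exclusion set over its time range.
#' @param min_span_s segments shorter than this (the smoothing window by
#'   default) carry no smoothed samples and are dropped.
#' @return One-row tibble: `value_hz_per_min`, `n_segments`,
#'   `total_time_min`, plus a `flag` set when no segment holds two defined
#'   samples.
#' @export
total_variation <- function(track, segments = NULL, min_span_s = 0) {
  if (is.null(segments)) {
    rng <- range(track$time)
    segments <- complement_intervals(attr(track, "exclusions"), rng)
  } else {
    # the caller's segmentation defines the period count M: validate and
    # sort, but never fuse adjacent periods
    segments <- arrange(as_tibble(segments)[, c("start", "end")], .data$start)
    stopifnot(all(segments$end >= segments$start))
  }
  if (min_span_s > 0)
    segments <- filter(segments, .data$end - .data$start >= min_span_s)

  num <- 0; den_s <- 0; m <- 0
  for (i in seq_len(nrow(segments))) {
    sel <- track$time >= segments$start[i] & track$time <= segments$end[i] &
      !is.na(track$value)
    if (sum(sel) < 2) next
    tt <- track$time[sel]; vv <- track$value[sel]
    keep <- extremum_indices(vv)
    num <- num + sum(abs(diff(vv[keep])))
    den_s <- den_s + (tt[length(tt)] - tt[1])
    m <- m + 1
  }
  if (m == 0 || den_s <= 0) {
    return(tibble(value_hz_per_min = NA_real_, n_segments = 0L,
                  total_time_min = 0, flag = "no_usable_segment"))
  }
  tibble(value_hz_per_min = num / (den_s / 60), n_segments = as.integer(m),
         total_time_min = den_s / 60, flag = NA_character_)
}

# Indices of the local-extremum discretization: both endpoints plus strict
# sign changes of consecutive differences; plateaus contribute their first
# sample (zero differences carry the preceding sign).
extremum_indices <- function(v) {
  n <- length(v)
  if (n <= 2) return(seq_len(n))
  d <- sign(diff(v))
  for (i in seq_along(d)[-1]) if (d[i] == 0) d[i] <- d[i - 1]
  turns <- which(d[-1] != d[-length(d)] & d[-1] != 0) + 1L
  sort(unique(c(1L, turns, n)))
}
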