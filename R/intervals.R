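# Interval sets are tibbles with numeric `start`, `end` columns (seconds,
# half-open [start, end)); always kept sorted and non-overlapping.

empty_intervals <- function() tibble(start = numeric(), end = numeric())

as_intervals <- function(x) {
  if (is.null(x) || (is.data.frame(x) && nrow(x) == 0)) return(empty_intervals())
  if (is.matrix(x)) x <- tibble(start = x[, 1], end = x[, 2])
  x <- as_tibble(x)[, c("start", "end")]
  stopifnot(all(x$end >= x$start))
  merge_intervals(x)
}

# Sort and fuse overlapping or touching intervals.
merge_intervals <- function(iv) {
  if (nrow(iv) == 0) return(empty_intervals())
  iv <- arrange(iv, .data$start)
  out_s <- iv$start[1]; out_e <- iv$end[1]
  if (nrow(iv) > 1) {
    for (i in 2:nrow(iv)) {
      if (iv$start[i] <= out_e[length(out_e)]) {
        out_e[length(out_e)] <- max(out_e[length(out_e)], iv$end[i])
      } else {
        out_s <- c(out_s, iv$start[i]); out_e <- c(out_e, iv$end[i])
      }
    }
  }
  tibble(start = out_s, end = out_e)
}

# Runs of TRUE in a sample mask -> intervals on the time axis. `dt` is the
# sampling step; a run [i..j] maps to [t[i], t[j] + dt).
intervals_from_mask <- function(mask, times) {
  mask[is.na(mask)] <- FALSE
  if (!any(mask)) return(empty_intervals())
  dt <- if (length(times) > 1) times[2] - times[1] else 0
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  tibble(start = times[starts[keep]], end = times[ends[keep]] + dt)
}

mask_from_intervals <- function(iv, times) {
  m <- rep(FALSE, length(times))
  for (i in seq_len(nrow(iv))) m <- m | (times >= iv$start[i] & times < iv$end[i])
  m
}

point_in_intervals <- function(t, iv) {
  res <- rep(FALSE, length(t))
  for (i in seq_len(nrow(iv))) res <- res | (t >= iv$start[i] & t < iv$end[i])
  res
}

clip_intervals <- function(iv, window) {
  if (nrow(iv) == 0) return(empty_intervals())
  out <- iv %>%
    mutate(start = pmax(.data$start, window[1]), end = pmin(.data$end, window[2])) %>%
    filter(.data$end > .data$start)
  out
}

interval_durations <- function(iv) if (nrow(iv) == 0) numeric() else iv$end - iv$start

# Complement of an interval set within a window.
complement_intervals <- function(iv, window) {
  iv <- clip_intervals(merge_intervals(iv), window)
  if (nrow(iv) == 0) return(tibble(start = window[1], end = window[2]))
  starts <- c(window[1], iv$end)
  ends <- c(iv$start, window[2])
  keep <- ends > starts
  tibble(start = starts[keep], end = ends[keep])
}

# Morphological erosion then dilation (opening) of a boolean mask with a
# centred structuring element of `width_samples` samples. Removes runs of TRUE
# shorter than the element without extending surviving runs.
morph_open <- function(mask, width_samples) {
  if (width_samples <= 1 || !any(mask)) return(mask)
  k <- as.integer(width_samples)
  n <- length(mask)
  # erosion: TRUE iff all samples in the window are TRUE
  cs <- cumsum(c(0, as.numeric(mask)))
  half_l <- (k - 1L) %/% 2L; half_r <- k - 1L - half_l
  lo <- pmax(seq_len(n) - half_l, 1L); hi <- pmin(seq_len(n) + half_r, n)
  win_sum <- cs[hi + 1L] - cs[lo]
  eroded <- win_sum == (hi - lo + 1L) & mask
  # dilation: TRUE iff any eroded sample in the window
  cs2 <- cumsum(c(0, as.numeric(eroded)))
  win_sum2 <- cs2[hi + 1L] - cs2[lo]
  win_sum2 > 0
}
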