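# Artifact flagging by a sliding-window power/MAD rule, and correction of the
# flagged windows by wavelet quantile normalization (WQN): the magnitudes of
# the wavelet coefficients of a corrupted segment are remapped, level by
# level, through the empirical quantile function of a neighbouring clean
# segment, signs preserved.

#' Flag motion artifacts by sliding-window power
#'
#' Mean signal power is computed per channel in sliding windows; a window is
#' flagged when its power exceeds the median window power by more than three
#' times the median absolute deviation (MAD) of the window powers. The rule
#' is one-sided: motion artifacts raise the power, whereas low-power windows
#' are physiology (iso-electric suppressions, the recovery decay) and must
#' not be "corrected". Strict inequality is used, so a perfectly constant
#' recording (MAD = 0) yields no artifacts. The exported mask is the union
#' over channels.
#'
#' @param record an [eeg_record()].
#' @param window_s window length in seconds (default 10).
#' @param overlap fractional overlap between consecutive windows (default 0.5).
#' @param k flagging multiple of the MAD (default 3).
#'
#' @return An object of class `artifact_mask`: a list with the per-channel
#'   window table (`windows`), the per-channel flagged intervals (`by_channel`,
#'   columns start_s/end_s/channel) and their union (`flagged`).
#' @export
detect_artifacts <- function(record, window_s = 10, overlap = 0.5, k = 3) {
  if (window_s <= 0) abort("`window_s` must be positive.")
  if (overlap < 0 || overlap >= 1) abort("`overlap` must be in [0, 1).")
  fs <- record$fs
  nw <- as.integer(round(window_s * fs))
  if (ncol(record$samples) < nw)
    abort("Record is shorter than one analysis window.")
  step <- max(1L, as.integer(round(nw * (1 - overlap))))
  starts <- seq(1L, ncol(record$samples) - nw + 1L, by = step)

  windows <- purrr::map(seq_along(record$channels), function(ch) {
    x <- record$samples[ch, ]
    pw <- vapply(starts, function(s) mean(x[s:(s + nw - 1L)]^2), numeric(1))
    med <- median(pw)
    mad_p <- median(abs(pw - med))
    tibble(
      channel = record$channels[ch],
      start = (starts - 1L) / fs,
      end = (starts - 1L + nw) / fs,
      power = pw,
      flagged = pw - med > k * mad_p
    )
  }) %>% bind_rows()

  by_channel <- windows %>%
    filter(.data$flagged) %>%
    select("start", "end", "channel")
  flagged <- merge_intervals(by_channel[, c("start", "end")])
  structure(list(window_s = window_s, overlap = overlap, k = k,
                 windows = windows, by_channel = by_channel,
                 flagged = flagged),
            class = "artifact_mask")
}

#' @export
print.artifact_mask <- function(x, ...) {
  cat(sprintf("<artifact_mask> %d flagged interval(s), %.1f s total\n",
              nrow(x$flagged), sum(interval_durations(x$flagged))))
  invisible(x)
}

# ---- Haar discrete wavelet transform (lifting-style, any length) ----------
# Pairs (x[2k-1], x[2k]) map to approximation (sum)/sqrt(2) and detail
# (difference)/sqrt(2); an odd trailing sample is carried to the next level
# unchanged, making the transform exactly invertible for arbitrary lengths.

haar_decompose <- function(x, levels) {
  s <- x; det <- vector("list", 0); odd <- logical(0)
  for (l in seq_len(levels)) {
    n <- length(s)
    if (n < 2) break
    m <- n %/% 2L
    o <- (n %% 2L) == 1L
    a <- (s[2 * seq_len(m) - 1] + s[2 * seq_len(m)]) / sqrt(2)
    d <- (s[2 * seq_len(m) - 1] - s[2 * seq_len(m)]) / sqrt(2)
    if (o) a <- c(a, s[n])
    det[[l]] <- d; odd <- c(odd, o); s <- a
  }
  list(approx = s, details = det, odd = odd)
}

haar_reconstruct <- function(dec) {
  s <- dec$approx
  for (l in rev(seq_along(dec$details))) {
    d <- dec$details[[l]]
    carry <- NULL
    if (dec$odd[l]) { carry <- s[length(s)]; s <- s[-length(s)] }
    out <- numeric(2 * length(d))
    out[2 * seq_along(d) - 1] <- (s + d) / sqrt(2)
    out[2 * seq_along(d)] <- (s - d) / sqrt(2)
    s <- c(out, carry)
  }
  s
}

# Remap |v| through the empirical quantile function of |ref|, keeping signs.
wqn_map <- function(v, ref) {
  if (length(v) == 0 || length(ref) == 0) return(v)
  p <- rank(abs(v), ties.method = "average") / length(v)
  sign(v) * as.numeric(quantile(abs(ref), probs = p, type = 7, names = FALSE))
}

# Candidate reference starts: clean runs of >= m samples, scanned outward
# from the artifact (preceding runs right-to-left, then following runs
# left-to-right). The first candidate passing `power_ok` wins; if none does,
# the nearest candidate is used regardless (a low-power reference is still
# better than none).
find_reference_start <- function(clean, i0, i1, m, power_ok = NULL) {
  r <- rle(clean)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  ok <- r$values & r$lengths >= m
  if (!any(ok)) return(NA_integer_)
  cs <- starts[ok]; ce <- ends[ok]
  cand <- integer(0)
  for (idx in rev(which(ce < i0)))
    cand <- c(cand, seq(ce[idx] - m + 1L, cs[idx], by = -m))
  for (idx in which(cs > i1))
    cand <- c(cand, seq(cs[idx], ce[idx] - m + 1L, by = m))
  if (length(cand) == 0) return(NA_integer_)
  if (!is.null(power_ok)) for (p in cand) if (power_ok(p)) return(p)
  cand[1]
}

#' Correct flagged intervals by wavelet quantile normalization
#'
#' Each flagged interval is decomposed with a Haar discrete wavelet transform
#' alongside the nearest clean interval of equal length (preceding preferred);
#' at every decomposition level, including the final approximation, the
#' coefficient magnitudes of the corrupted segment are remapped through the
#' empirical quantile function of the reference coefficients with signs
#' preserved, and the segment is reconstructed. The reference must also
#' resemble typical background activity (mean power at least 30 percent of
#' the record's median 10 s chunk power): without that check an artifact
#' next to an iso-electric suppression would be remapped onto the flat epoch
#' and come out flat itself; if no candidate passes, the nearest clean
#' interval is used regardless. Unflagged samples are untouched. Intervals
#' without a clean reference of sufficient length are left uncorrected with
#' a warning.
#'
#' @param record an [eeg_record()].
#' @param mask an [detect_artifacts()] mask for the same record.
#' @param wavelet_levels number of decomposition levels (default 5, capped at
#'   what the interval length allows).
#'
#' @return A corrected [eeg_record()].
#' @export
wqn_correct <- function(record, mask, wavelet_levels = 5) {
  stopifnot(inherits(mask, "artifact_mask"))
  iv <- mask$flagged
  if (nrow(iv) == 0) return(record)
  fs <- record$fs
  n <- ncol(record$samples)
  clean <- !mask_from_intervals(iv, record_times(record))
  out <- record$samples
  # typical background level: median mean power over 10 s chunks
  avg_pow <- colMeans(record$samples^2)
  chunk <- as.integer(10 * fs)
  n_chunks <- n %/% chunk
  chunk_pow <- vapply(seq_len(n_chunks), function(j)
    mean(avg_pow[((j - 1) * chunk + 1):(j * chunk)]), numeric(1))
  med_pow <- median(chunk_pow)
  for (i in seq_len(nrow(iv))) {
    i0 <- max(1L, as.integer(floor(iv$start[i] * fs)) + 1L)
    i1 <- min(n, as.integer(ceiling(iv$end[i] * fs)))
    m <- i1 - i0 + 1L
    power_ok <- function(p) mean(avg_pow[p:(p + m - 1L)]) >= 0.3 * med_pow
    r0 <- find_reference_start(clean, i0, i1, m, power_ok)
    if (is.na(r0)) {
      warn(sprintf("No clean reference of %.1f s for artifact at %.1f-%.1f s; left uncorrected.",
                   m / fs, iv$start[i], iv$end[i]))
      next
    }
    lv <- min(wavelet_levels, max(1L, floor(log2(m)) - 1L))
    for (ch in seq_len(nrow(out))) {
      dec_a <- haar_decompose(out[ch, i0:i1], lv)
      dec_r <- haar_decompose(record$samples[ch, r0:(r0 + m - 1L)], lv)
      for (l in seq_along(dec_a$details))
        dec_a$details[[l]] <- wqn_map(dec_a$details[[l]], dec_r$details[[l]])
      dec_a$approx <- wqn_map(dec_a$approx, dec_r$approx)
      out[ch, i0:i1] <- haar_reconstruct(dec_a)
    }
  }
  rec <- record
  rec$samples <- out
  rec
}
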