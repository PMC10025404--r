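# Shared fixtures, built in code at test time.

# Quick 4-channel record of superposed tones (identical channels).
tone_record <- function(freqs, amps, fs = 250, duration_s = 60,
                        noise_sd = 0) {
  t <- (seq_len(round(duration_s * fs)) - 1) / fs
  x <- rep(0, length(t))
  for (i in seq_along(freqs)) x <- x + amps[i] * sin(2 * pi * freqs[i] * t)
  if (noise_sd > 0) x <- x + rnorm(length(t), 0, noise_sd)
  eeg_record(rbind(x, x, x, x), fs = fs)
}

# Compact synthetic patient for unit tests (shorter phases than the cohort
# defaults, so each test record synthesizes in well under a second).
quick_spec <- function(...) {
  synth_spec(induction_s = 240, maintenance_s = 420, recovery_s = 780,
             dt_roc_min = 6, t_in_offset_s = 90, ...)
}

# deterministic construction of a pair with an exact Pearson coefficient
pair_with_r <- function(r, n) {
  x <- scale(seq_len(n))[, 1]
  e <- scale(resid(lm(rnorm(n) ~ x)))[, 1]
  list(x = x, y = r * x + sqrt(1 - r^2) * e)
}

# independent Romberg quadrature of the Zellner-Siow integral (same
# substitution, different integrator)
romberg_bf01 <- function(r, n, p = 1) {
  f <- function(u) {
    g <- u / (1 - u)
    exp(((n - p - 1) / 2) * log1p(g) - ((n - 1) / 2) * log1p((1 - r^2) * g) -
          1.5 * log(g) - n / (2 * g)) / (1 - u)^2
  }
  I <- pracma::romberg(f, 1e-12, 1 - 1e-9, tol = 1e-10)$value
  1 / (sqrt(n / 2) / gamma(0.5) * I)
}

interval_lengths_within <- function(iv, window) {
  s <- pmax(iv$start, window[1]); e <- pmin(iv$end, window[2])
  pmax(e - s, 0)
}

# Hand-built spectrogram object for band-arithmetic tests.
flat_spectrogram <- function(value = 1, freqs = seq(0, 45, by = 0.05),
                             times = seq(10, 100, by = 5)) {
  structure(list(times = times, freqs = freqs,
                 power = matrix(value, nrow = length(freqs),
                                ncol = length(times)),
                 window_s = 20, overlap = 0.75,
                 weights = c(F7 = 0.5, Fp1 = 1, Fp2 = 1, F8 = 0.5), fs = 250),
            class = "eeg_spectrogram")
}

# Default children cohort shared by the heavier recovery tests; generated
# once per test session.
.cohort_cache <- new.env(parent = emptyenv())
shared_children_features <- function(n = 50, seed = 20240915) {
  key <- sprintf("feat_%d_%d", n, seed)
  if (is.null(.cohort_cache[[key]])) {
    cohort <- synthesize_cohort(n, group = "children", seed = seed,
                                records = FALSE)
    rows <- vector("list", n); segs <- vector("list", n)
    for (i in seq_len(n)) {
      rec <- record_for_patient(cohort, i)
      pf <- run_patient(rec, patient_id = cohort$truth$patient_id[i],
                        keep_intermediates = TRUE)
      segs[[i]] <- attr(pf, "intermediates")$segments
      attr(pf, "intermediates") <- NULL
      rows[[i]] <- pf
    }
    .cohort_cache[[key]] <- list(truth = cohort$truth,
                                 specs = cohort$specs,
                                 features = do.call(rbind, rows),
                                 segments = segs)
  }
  .cohort_cache[[key]]
}
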