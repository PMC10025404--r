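# Spectrogram, band powers, peak-frequency tracks, Savitzky-Golay smoothing.

test_that("a pure tone peaks at its frequency in every window", {
  rec <- tone_record(10, 40, duration_s = 100)
  spg <- spectrogram(rec)
  peaks <- spg$freqs[apply(spg$power, 2, which.max)]
  expect_true(all(abs(peaks - 10) < 0.06))
})

test_that("identical channels make the weighted mean equal any channel weighting", {
  set.seed(2)
  rec <- tone_record(c(2, 10), c(20, 10), duration_s = 60, noise_sd = 2)
  s1 <- spectrogram(rec)
  s2 <- spectrogram(rec, weights = c(F7 = 1, Fp1 = 1, Fp2 = 1, F8 = 1))
  expect_equal(s1$power, s2$power, tolerance = 1e-12)
})

test_that("integrated spectrogram energy matches a Parseval oracle on the same taper", {
  set.seed(3)
  x <- rnorm(250 * 60)
  rec <- eeg_record(rbind(x, x, x, x), fs = 250)
  spg <- spectrogram(rec, max_freq = 125)
  nw <- 20 * 250
  w <- 0.5 * (1 - cos(2 * pi * seq(0, nw - 1) / nw))
  starts <- seq(1, length(x) - nw + 1, by = nw / 4)
  # oracle: taper-weighted mean square per window
  oracle <- vapply(starts, function(s)
    sum((x[s:(s + nw - 1)] * w)^2) / sum(w^2), numeric(1))
  df <- diff(spg$freqs[1:2])
  est <- apply(spg$power, 2, function(p) sum((p[-1] + p[-length(p)]) / 2) * df)
  expect_equal(est, oracle, tolerance = 0.05, ignore_attr = TRUE)
})

test_that("band power integrates the spectral density over the band", {
  spg <- flat_spectrogram(1)
  expect_equal(band_power(spg, c(0.1, 4))$value, rep(3.9, 19))
  expect_equal(band_power(spg, c(8, 12))$value, rep(4.0, 19))
  expect_error(band_power(spg, c(40, 60)), "outside")
})

test_that("band power is local: a one-bin spike contributes only to its band", {
  spg <- flat_spectrogram(0)
  df <- 0.05
  m <- 2.5                                 # spike mass
  spg$power[spg$freqs == 10, ] <- m / df   # trapezoidal mass ~ height * df
  a <- band_power(spg, c(8, 12))$value
  d <- band_power(spg, c(0.1, 4))$value
  expect_equal(a, rep(m, length(a)), tolerance = 1e-9)
  expect_equal(d, rep(0, length(d)))
})

test_that("relative band power reduces to the band-width ratio for flat spectra", {
  spg <- flat_spectrogram(3)
  rel <- relative_band_power(spg, c(8, 12))
  expect_equal(rel$value, rep(100 * 4 / 44.9, length(rel$value)),
               tolerance = 1e-9)
  # all energy inside the band -> 100 %
  spg2 <- flat_spectrogram(0)
  spg2$power[spg2$freqs >= 8 & spg2$freqs <= 12, ] <- 5
  expect_equal(relative_band_power(spg2, c(8, 12))$value,
               rep(100, ncol(spg2$power)), tolerance = 0.5)
})

test_that("maintenance relative alpha power matches the generator's energy accounting", {
  # amplitudes chosen so the analytic alpha/total energy ratio is ~12 %
  spec <- quick_spec(delta_amp_uv = 30, alpha_amp_uv = 11.2,
                     freq_wander_sd_hz = 0.1, channel_gain_sd = 0)
  rec <- synthesize_record(spec, seed = 23)
  spg <- spectrogram(rec)
  expected <- 100 * synth_band_energy(spec, c(8, 12)) /
    synth_band_energy(spec, c(0.1, 45))
  expect_equal(expected, 12, tolerance = 0.05)
  # window kept clear of the delta decay's leading tail
  got <- mean_band_power(relative_band_power(spg, c(8, 12)), c(300, 450))
  expect_lt(abs(got - expected), 1)
})

test_that("peak frequency follows a moving peak, honours exclusions and tie-breaks low", {
  freqs <- seq(0, 45, by = 0.05)
  times <- seq(0, 95, by = 5)
  power <- matrix(0, length(freqs), length(times))
  ramp <- seq(10, 12, length.out = length(times))
  for (j in seq_along(times))
    power[which.min(abs(freqs - ramp[j])), j] <- 1
  spg <- flat_spectrogram(0); spg$power <- power; spg$times <- times
  tr <- peak_frequency(spg, c(8, 12))
  expect_equal(tr$value, ramp, tolerance = 0.05)

  tr2 <- peak_frequency(spg, c(8, 12),
                        exclusions = data.frame(start = 20, end = 40))
  expect_true(all(is.na(tr2$value[tr2$time >= 20 & tr2$time < 40])))
  expect_true(all(!is.na(tr2$value[tr2$time < 20])))

  # exact tie between two bins: lowest frequency wins
  spg$power[] <- 0
  spg$power[c(which.min(abs(freqs - 9)), which.min(abs(freqs - 11))), ] <- 1
  expect_equal(peak_frequency(spg, c(8, 12))$value[1], 9, tolerance = 0.05)
})

test_that("peak frequency is invariant to rescaling the spectrogram", {
  spec <- quick_spec()
  rec <- synthesize_record(spec, seed = 29)
  spg <- spectrogram(rec)
  tr1 <- peak_frequency(spg, c(8, 12))
  spg$power <- spg$power * 17.3
  expect_identical(tr1$value, peak_frequency(spg, c(8, 12))$value)
})

test_that("Savitzky-Golay smoothing preserves linear and constant tracks", {
  t <- seq(0, 600, by = 5)
  lin <- gaeeg:::new_freq_track(t, 9 + 0.002 * t, c(8, 12),
                                gaeeg:::empty_intervals(), FALSE)
  sm <- sg_smooth(lin)
  expect_equal(sm$value, 9 + 0.002 * sm$time, tolerance = 1e-9)
  const <- gaeeg:::new_freq_track(t, rep(10, length(t)), c(8, 12),
                                  gaeeg:::empty_intervals(), FALSE)
  expect_equal(sg_smooth(const)$value, rep(10, length(t)), tolerance = 1e-12)
})

test_that("smoothing suppresses fast oscillations and keeps slow ones", {
  t <- seq(0, 1200, by = 1)
  slow <- 0.8 * sin(2 * pi * t / 1200)          # 20 min period
  fast <- 0.5 * sin(2 * pi * t / 10)            # 10 s period
  tr <- gaeeg:::new_freq_track(t, 10 + slow + fast, c(8, 12),
                               gaeeg:::empty_intervals(), FALSE)
  sm <- sg_smooth(tr)
  ok <- !is.na(sm$value)
  # the fast component (rms 0.354 Hz) must be attenuated at least 10-fold
  resid <- sm$value[ok] - (10 + 0.8 * sin(2 * pi * sm$time[ok] / 1200))
  expect_lt(sqrt(mean(resid^2)), 0.5 / sqrt(2) / 10 + 0.02)
  # the slow component survives within 10 %
  amp_at <- function(tt, v, period) {
    cc <- cos(2 * pi * tt / period); ss <- sin(2 * pi * tt / period)
    fit <- lm(v ~ cc + ss)
    sqrt(sum(coef(fit)[2:3]^2))
  }
  expect_equal(amp_at(sm$time[ok], sm$value[ok], 1200), 0.8, tolerance = 0.1)
})

test_that("smoothing is gap-aware: isolated windows stay undefined", {
  t <- seq(0, 300, by = 5)
  v <- rep(10, length(t))
  v[t > 100 & t < 260] <- NA          # long gap
  tr <- gaeeg:::new_freq_track(t, v, c(8, 12),
                               data.frame(start = 100, end = 260), FALSE)
  sm <- sg_smooth(tr)
  expect_true(all(is.na(sm$value[sm$time >= 100 & sm$time < 260])))
  expect_true(all(!is.na(sm$value[sm$time <= 40])))
})

test_that("band power is additive over a partition of the full range", {
  spec <- quick_spec()
  rec <- synthesize_record(spec, seed = 37)
  spg <- spectrogram(rec)
  total <- band_power(spg, c(0.1, 45))$value
  parts <- Reduce(`+`, lapply(list(c(0.1, 4), c(4, 8), c(8, 12), c(12, 45)),
                              function(b) band_power(spg, b)$value))
  expect_equal(parts, total, tolerance = 1e-9)
  rel_total <- relative_band_power(spg, c(0.1, 45))$value
  expect_equal(rel_total, rep(100, length(rel_total)), tolerance = 1e-9)
})
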