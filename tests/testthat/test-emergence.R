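# Sigmoid fitting of the recovery band-power decays and emergence markers.

sigmoid_series <- function(a, b, c, t0, t = seq(0, 1200, by = 5), noise = 0) {
  tibble::tibble(time = t,
                 value = a / (1 + exp(c * (t - t0))) + b +
                   rnorm(length(t), 0, noise))
}

test_that("noiseless sigmoids are recovered to high precision", {
  s <- sigmoid_series(a = 5, b = 1, c = 0.02, t0 = 600)
  fit <- fit_sigmoid(s, window = c(0, 1200))
  expect_lt(abs(fit$a - 5) / 5, 1e-3)
  expect_lt(abs(fit$b - 1) / 1, 1e-3)
  expect_lt(abs(fit$c - 0.02) / 0.02, 1e-3)
  expect_lt(abs(fit$t0 - 600), 0.5)
  expect_false(fit$no_transition)
})

test_that("the centre is located within 30 s under heavy noise", {
  set.seed(61)
  errs <- replicate(100, {
    s <- sigmoid_series(a = 5, b = 1, c = 0.02, t0 = 600, noise = 0.2 * 5)
    fit_sigmoid(s, window = c(0, 1200))$t0 - 600
  })
  expect_lt(median(abs(errs)), 30)
})

test_that("constant series degenerate to the flagged no-transition branch", {
  s <- tibble::tibble(time = seq(0, 1200, 5), value = rep(3, 241))
  fit <- fit_sigmoid(s, window = c(0, 1200))
  expect_true(fit$no_transition)
  expect_equal(fit$a, 0)
  expect_equal(fit$b, 3)
  expect_error(threshold_crossing(fit), "slope")
})

test_that("fits need a minimally covered window", {
  s <- sigmoid_series(5, 1, 0.02, 600, t = seq(0, 100, by = 20))
  expect_error(fit_sigmoid(s, window = c(0, 100)), "20 samples")
})

test_that("the closed-form crossing matches its algebra and a bisection oracle", {
  fit <- structure(list(a = 5, b = 1, c = 1, t0 = 0, no_transition = FALSE),
                   class = "sigmoid_fit")
  expect_equal(threshold_crossing(fit, 0.5), 0)
  expect_equal(threshold_crossing(fit, 0.05), log(19), tolerance = 1e-12)

  fit2 <- structure(list(a = 4.2, b = 0.7, c = 0.017, t0 = 812,
                         no_transition = FALSE),
                    class = "sigmoid_fit")
  for (lam in c(0.05, 0.2, 0.8)) {
    target <- fit2$a * lam + fit2$b
    f <- function(t) fit2$a / (1 + exp(fit2$c * (t - fit2$t0))) + fit2$b - target
    lo <- fit2$t0 - 2000; hi <- fit2$t0 + 2000
    for (i in 1:80) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) lo <- mid else hi <- mid
    }
    expect_lt(abs(threshold_crossing(fit2, lam) - (lo + hi) / 2), 1e-6)
  }
})

test_that("the crossing time decreases strictly in lambda", {
  fit <- structure(list(a = 3, b = 0.5, c = 0.03, t0 = 500,
                        no_transition = FALSE),
                   class = "sigmoid_fit")
  lams <- seq(0.05, 0.95, by = 0.1)
  tc <- vapply(lams, function(l) threshold_crossing(fit, l), numeric(1))
  expect_true(all(diff(tc) < 0))
})

test_that("markers combine the two fits and the peak-frequency track", {
  delta_fit <- structure(list(a = 8, b = 1, c = 0.025, t0 = 500,
                              no_transition = FALSE), class = "sigmoid_fit")
  alpha_fit <- structure(list(a = 4, b = 0.5, c = 0.02, t0 = 800,
                              no_transition = FALSE), class = "sigmoid_fit")
  t_in <- 500 + log(19) / 0.025
  t_out <- 800 + log(19) / 0.02
  tt <- seq(0, 1500, by = 5)
  ramp <- approx(c(t_in, t_out), c(9.5, 12.8), xout = tt, rule = 2)$y
  fmax <- gaeeg:::new_freq_track(tt, ramp, c(8, 30),
                                 gaeeg:::empty_intervals(), FALSE)
  mk <- emergence_markers(delta_fit, alpha_fit, fmax)
  expect_equal(mk$t_in_s, t_in, tolerance = 1e-9)
  expect_equal(mk$t_out_s, t_out, tolerance = 1e-9)
  expect_equal(mk$dt_roc_min, (t_out - t_in) / 60, tolerance = 1e-9)
  expect_equal(mk$df_roc_hz, 3.3, tolerance = 0.3)
  expect_true(is.na(mk$flag))

  flat <- gaeeg:::new_freq_track(tt, rep(10, length(tt)), c(8, 30),
                                 gaeeg:::empty_intervals(), FALSE)
  expect_equal(emergence_markers(delta_fit, alpha_fit, flat)$df_roc_hz, 0)

  # alpha finishing before delta is reported but flagged
  mk2 <- emergence_markers(alpha_fit, delta_fit, flat)
  expect_equal(mk2$flag, "inconsistent_transition")
})

test_that("time-shifting the series shifts the markers and nothing else", {
  set.seed(67)
  noise_d <- rnorm(241, 0, 0.3); noise_a <- rnorm(241, 0, 0.2)
  t <- seq(0, 1200, by = 5)
  mk_for <- function(shift) {
    sd_ <- tibble::tibble(time = t + shift,
                          value = 8 / (1 + exp(0.02 * (t - 500))) + 1 + noise_d)
    sa_ <- tibble::tibble(time = t + shift,
                          value = 4 / (1 + exp(0.02 * (t - 800))) + 0.5 + noise_a)
    fd <- fit_sigmoid(sd_, window = c(shift, shift + 1200))
    fa <- fit_sigmoid(sa_, window = c(shift, shift + 1200))
    fmax <- gaeeg:::new_freq_track(t + shift, 10 + t / 400, c(8, 30),
                                   gaeeg:::empty_intervals(), FALSE)
    emergence_markers(fd, fa, fmax)
  }
  m0 <- mk_for(0); m1 <- mk_for(300)
  expect_equal(m1$t_in_s - m0$t_in_s, 300, tolerance = 0.5)
  expect_equal(m1$t_out_s - m0$t_out_s, 300, tolerance = 0.5)
  expect_equal(m1$dt_roc_min, m0$dt_roc_min, tolerance = 0.01)
})

test_that("tidy and glance summarize a fit", {
  s <- sigmoid_series(5, 1, 0.02, 600)
  fit <- fit_sigmoid(s, window = c(0, 1200))
  td <- tidy(fit)
  expect_equal(td$term, c("a", "b", "c", "t0"))
  expect_equal(nrow(glance(fit)), 1)
})
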