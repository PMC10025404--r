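# Sigmoid fits of the band-power decays during recovery of consciousness and
# the emergence-trajectory markers derived from them. The model is
# S(t) = a / (1 + exp(c (t - t0))) + b with a > 0 and c > 0 encoding a decay
# from the a + b plateau down to the b floor.

#' Fit a decaying sigmoid to a band-power series
#'
#' Least-squares fit of `a / (1 + exp(c (t - t0))) + b` over the analysis
#' window (by default the final 20 min of the series), minimizing the
#' discretized squared-error integral with Levenberg-Marquardt iterations
#' from a multi-start grid: `t0` over five quantiles of the window, `c` in
#' {0.005, 0.02, 0.1} / s, amplitude and baseline from the series quartiles;
#' `a` and `c` are bounded positive. The best fit by residual sum of squares
#' is returned. A series with (near-)zero amplitude range degenerates to the
#' `a = 0` branch and is flagged `no_transition`.
#'
#' @param series a [band_power()] series (tibble with `time`, `value`).
#' @param window numeric length-2 time window (s); default the last 20 min.
#' @param window_min window span (min) used when `window` is `NULL`.
#' @return Object of class `sigmoid_fit` with elements `a`, `b`, `c`, `t0`,
#'   `rss`, `n`, `window`, `no_transition`, `data`.
#' @export
fit_sigmoid <- function(series, window = NULL, window_min = 20) {
  if (is.null(window)) {
    tf <- max(series$time)
    window <- c(tf - window_min * 60, tf)
  }
  sel <- series$time >= window[1] & series$time <= window[2] &
    !is.na(series$value)
  t <- series$time[sel]; v <- series$value[sel]
  if (length(t) < 20) abort("Need at least 20 samples in the fit window.")
  rng <- diff(range(v))
  dat <- tibble(time = t, value = v)

  if (rng <= .Machine$double.eps * (1 + max(abs(v)))) {
    fit <- list(a = 0, b = mean(v), c = NA_real_, t0 = NA_real_,
                rss = 0, n = length(t), window = window,
                no_transition = TRUE, band = attr(series, "band"),
                data = dat)
    return(structure(fit, class = "sigmoid_fit"))
  }

  q <- quantile(v, c(0.1, 0.25, 0.75, 0.9), names = FALSE)
  a0 <- max(q[4] - q[1], rng / 4)
  b0 <- q[1]
  starts <- expand.grid(
    t0 = quantile(t, c(0.1, 0.3, 0.5, 0.7, 0.9), names = FALSE),
    c = c(0.005, 0.02, 0.1)
  )
  span <- diff(window)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        value ~ a / (1 + exp(c * (time - t0))) + b,
        data = dat,
        start = list(a = a0, b = b0, c = starts$c[i], t0 = starts$t0[i]),
        lower = c(a = 0, b = -Inf, c = 1e-5, t0 = window[1] - 2 * span),
        upper = c(a = Inf, b = Inf, c = 5, t0 = window[2] + 2 * span),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(resid(fit)^2)
      if (is.null(best) || rss < best$rss)
        best <- list(coefs = coef(fit), rss = rss)
    }
  }
  if (is.null(best))
    abort("Sigmoid fit failed to converge from every start.")
  cf <- best$coefs
  no_trans <- cf[["a"]] <= 1e-3 * rng
  structure(list(a = cf[["a"]], b = cf[["b"]], c = cf[["c"]],
                 t0 = cf[["t0"]], rss = best$rss, n = length(t),
                 window = window, no_transition = no_trans,
                 band = attr(series, "band"), data = dat),
            class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf("<sigmoid_fit> a=%.3g b=%.3g c=%.4g /s t0=%.1f s (rss %.3g, n %d)%s\n",
              x$a, x$b, x$c, x$t0, x$rss, x$n,
              if (isTRUE(x$no_transition)) " [no transition]" else ""))
  invisible(x)
}

#' @export
tidy.sigmoid_fit <- function(x, ...) {
  tibble(term = c("a", "b", "c", "t0"),
         estimate = c(x$a, x$b, x$c, x$t0))
}

#' @export
glance.sigmoid_fit <- function(x, ...) {
  tibble(rss = x$rss, n = x$n, no_transition = x$no_transition,
         window_start = x$window[1], window_end = x$window[2])
}

#' Predicted sigmoid values
#' @param object a [fit_sigmoid()] object.
#' @param times evaluation times (s).
#' @param ... unused.
#' @return Numeric vector.
#' @export
predict.sigmoid_fit <- function(object, times = object$data$time, ...) {
  if (isTRUE(object$no_transition)) return(rep(object$b, length(times)))
  object$a / (1 + exp(pmin(500, object$c * (times - object$t0)))) + object$b
}

#' Closed-form sigmoid threshold crossing
#'
#' The first time where the fitted decay reaches `a * lambda + b`, i.e. the
#' point with a fraction `lambda` of the transient amplitude left:
#' `t = t0 + ln(1/lambda - 1) / c`.
#'
#' @param fit a [fit_sigmoid()] object.
#' @param lambda remaining-amplitude fraction in (0, 1), default 0.05.
#' @return Crossing time (s).
#' @export
threshold_crossing <- function(fit, lambda = 0.05) {
  if (lambda <= 0 || lambda >= 1) abort("`lambda` must be in (0, 1).")
  if (is.na(fit$c) || fit$c == 0)
    abort("Fit has zero slope; no crossing defined.")
  fit$t0 + log(1 / lambda - 1) / fit$c
}

lookup_track <- function(track, t0, max_gap_s = 30) {
  def <- !is.na(track$value)
  if (!any(def)) return(NA_real_)
  td <- track$time[def]; vd <- track$value[def]
  i <- which.min(abs(td - t0))
  if (abs(td[i] - t0) <= max_gap_s) return(vd[i])
  approx(td, vd, xout = t0, rule = 2)$y
}

#' Emergence-trajectory markers
#'
#' `t_in` is the 5 %-remaining crossing of the delta-band power fit (end of
#' the delta plateau), `t_out` the 5 %-remaining crossing of the alpha-band
#' power fit (alpha reaching its lower plateau). The duration shift is
#' `dt_roc = (t_out - t_in) / 60` minutes and the frequency shift
#' `df_roc = f_max(t_out) - f_max(t_in)` Hz, with the peak-frequency track
#' looked up at the nearest defined sample within 30 s (linear interpolation
#' across wider gaps). If `t_out <= t_in` the markers are still reported,
#' flagged `inconsistent`.
#'
#' @param delta_fit,alpha_fit [fit_sigmoid()] objects for the delta- and
#'   alpha-band powers.
#' @param fmax a [peak_frequency()] track on the 8-30 Hz band.
#' @param lambda_in,lambda_out remaining-amplitude fractions (default 0.05).
#' @return One-row tibble: `t_in_s`, `t_out_s`, `dt_roc_min`, `df_roc_hz`,
#'   `fmax_in_hz`, `fmax_out_hz`, `flag`.
#' @export
emergence_markers <- function(delta_fit, alpha_fit, fmax,
                              lambda_in = 0.05, lambda_out = 0.05) {
  t_in <- threshold_crossing(delta_fit, lambda_in)
  t_out <- threshold_crossing(alpha_fit, lambda_out)
  f_in <- lookup_track(fmax, t_in)
  f_out <- lookup_track(fmax, t_out)
  flag <- if (t_out <= t_in) "inconsistent_transition" else NA_character_
  tibble(
    t_in_s = t_in, t_out_s = t_out,
    dt_roc_min = (t_out - t_in) / 60,
    df_roc_hz = f_out - f_in,
    fmax_in_hz = f_in, fmax_out_hz = f_out,
    flag = flag
  )
}
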