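# Synthetic anesthesia-EEG generator. Each record is the sum of a
# narrowband amplitude-modulated delta oscillation, an alpha oscillation whose
# peak frequency ramps upward during recovery ("zip" shape), and 1/f
# background noise; planted iso-electric suppressions (IES), alpha
# suppressions and motion-artifact bursts are applied as smooth gates. Band
# powers during recovery follow exact logistic decays, so the true emergence
# markers t_in / t_out are well defined and carried in the annotations.

with_seed_local <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

raised_cosine_gate <- function(times, iv, edge_s = 0.5) {
  # 1 outside the intervals, 0 inside, half-cosine edges of width edge_s
  g <- rep(1, length(times))
  for (i in seq_len(nrow(iv))) {
    s <- iv$start[i]; e <- iv$end[i]
    inside <- times >= s & times < e
    g[inside] <- 0
    fall <- times >= (s - edge_s) & times < s
    g[fall] <- pmin(g[fall], 0.5 * (1 + cos(pi * (times[fall] - (s - edge_s)) / edge_s)))
    rise <- times >= e & times < (e + edge_s)
    g[rise] <- pmin(g[rise], 0.5 * (1 - cos(pi * (times[rise] - e) / edge_s)))
  }
  g
}

# 1/f^e background noise by spectral shaping: one-sided PSD proportional to
# f^-e above f_c (flat below), normalized to an exact total `rms`. The band
# fraction of the total power is given in closed form by colored_band_fraction(),
# which the analytic energy accounting in synth_band_energy() relies on.
colored_noise <- function(n, fs, rms, exponent = 1.8, f_c = 0.1) {
  if (rms <= 0) return(numeric(n))
  # keep the FFT on a fast, even length (the Hermitian-extension logic below
  # assumes an even nfft)
  nfft <- stats::nextn(n, c(2, 3, 5))
  while (nfft %% 2 == 1) nfft <- stats::nextn(nfft + 1, c(2, 3, 5))
  freqs <- seq(0, fs / 2, by = fs / nfft)
  shape <- pmax(freqs, f_c)^(-exponent / 2)
  shape[1] <- 0
  nf <- length(freqs)
  re <- rnorm(nf); im <- rnorm(nf)
  spec <- complex(real = re, imaginary = im) * shape
  spec[1] <- 0
  if (nfft %% 2 == 0) spec[nf] <- complex(real = re[nf], imaginary = 0) * shape[nf]
  full <- c(spec, Conj(rev(spec[2:(nf - 1)])))
  x <- Re(fft(full, inverse = TRUE)) / nfft
  x <- x[seq_len(n)]
  x * rms / sqrt(mean(x^2))
}

# integral of f^-e over [f1, f2] (f1 >= f_c assumed for band queries)
shape_integral <- function(f1, f2, exponent) {
  if (abs(exponent - 1) < 1e-12) log(f2 / f1)
  else (f1^(1 - exponent) - f2^(1 - exponent)) / (exponent - 1)
}

colored_band_fraction <- function(band, fs, exponent = 1.8, f_c = 0.1) {
  total <- f_c * f_c^(-exponent) + shape_integral(f_c, fs / 2, exponent)
  shape_integral(max(band[1], f_c), band[2], exponent) / total
}

# smooth random frequency wander: white noise drawn on a coarse 2 Hz grid,
# moving-average smoothed with time constant tau_s, interpolated to fs
slow_wander <- function(n, fs, sd_hz, tau_s = 45) {
  if (sd_hz <= 0) return(rep(0, n))
  fs2 <- 2
  n2 <- ceiling(n * fs2 / fs) + 2L
  k <- max(2L, as.integer(round(tau_s * fs2)))
  w <- rnorm(n2 + k)
  cs <- cumsum(w)
  sm <- (cs[(k + 1):(k + n2)] - cs[1:n2]) / k
  sm <- sm * sd_hz / sd(sm)
  t2 <- (seq_len(n2) - 1) / fs2
  approx(t2, sm, xout = (seq_len(n) - 1) / fs, rule = 2)$y
}

#' Per-patient synthesis specification
#'
#' Assembles and validates the phase plan and band model for one synthetic
#' patient. Defaults describe a compact pediatric case: 10 min induction,
#' 15 min maintenance, 20 min recovery, with the delta- and alpha-band powers
#' decaying as logistic functions of time during recovery (delta first) and
#' the alpha peak frequency ramping linearly by `df_roc_hz` between the true
#' markers.
#'
#' @param fs sampling rate (Hz), default 250.
#' @param induction_s induction duration (s).
#' @param maintenance_s maintenance duration (s); anesthesia recordings are
#'   maintenance-dominated, which the sliding-power artifact statistics rely
#'   on.
#' @param recovery_s recovery duration (s); the recording ends at its end.
#' @param extubation_delay_min delay from hypnotic-off to extubation (min).
#' @param delta_amp_uv,alpha_amp_uv maintenance tone amplitudes (microvolts).
#' @param delta_freq_hz,alpha_freq_hz maintenance peak frequencies (Hz).
#' @param delta_floor,alpha_floor recovery floor of band power as a fraction
#'   of the decaying amplitude (power units).
#' @param c_delta,c_alpha logistic decay slopes (1/s).
#' @param t_in_offset_s true t_in relative to hypnotic-off (s).
#' @param dt_roc_min true emergence duration shift (min).
#' @param df_roc_hz true emergence frequency shift (Hz).
#' @param em_frac amplitude fraction of the emergence tone that carries the
#'   upward peak-frequency ramp, relative to the alpha core.
#' @param freq_wander_sd_hz slow wander of the peak frequencies (Hz, sd).
#' @param awake_amp_uv amplitude of the awake beta activity that fades at
#'   loss of consciousness (microvolts).
#' @param noise_rms_uv background noise level (microvolts rms).
#' @param noise_exponent spectral exponent e of the 1/f^e background.
#' @param ies_floor_rms_uv residual amplitude inside IES (microvolts rms).
#' @param bolus_ies,spontaneous_ies,alpha_suppressions,artifact_bursts
#'   interval tables (`start`, `end` in s); artifacts also take a `gain`
#'   column (multiple of the ongoing-EEG rms, default 10).
#' @param channel_gain_sd per-channel multiplicative gain spread.
#'
#' @return A list of class `eeg_synth_spec`.
#' @export
synth_spec <- function(fs = 250,
                       induction_s = 600,
                       maintenance_s = 1800,
                       recovery_s = 1200,
                       extubation_delay_min = 10,
                       delta_amp_uv = 30,
                       alpha_amp_uv = 18,
                       delta_freq_hz = 2,
                       alpha_freq_hz = 10,
                       delta_floor = 0.02,
                       alpha_floor = 0.02,
                       c_delta = 0.025,
                       c_alpha = 0.02,
                       t_in_offset_s = 120,
                       dt_roc_min = 7.8,
                       df_roc_hz = 3.3,
                       em_frac = 0.4,
                       freq_wander_sd_hz = 0.3,
                       awake_amp_uv = 15,
                       noise_rms_uv = 3,
                       noise_exponent = 1.8,
                       ies_floor_rms_uv = 1,
                       bolus_ies = NULL,
                       spontaneous_ies = NULL,
                       alpha_suppressions = NULL,
                       artifact_bursts = NULL,
                       channel_gain_sd = 0.05) {
  if (any(c(induction_s, maintenance_s, recovery_s) <= 0))
    abort("Phase durations must be positive.")
  if (fs < 128) abort("`fs` must be >= 128 Hz.")
  if (dt_roc_min <= 0) abort("`dt_roc_min` must be positive.")
  duration <- induction_s + maintenance_s + recovery_s
  recovery_start <- induction_s + maintenance_s
  t_in <- recovery_start + t_in_offset_s
  t_out <- t_in + dt_roc_min * 60
  if (t_out >= duration)
    abort("True t_out falls beyond the end of the recording; shorten `dt_roc_min` or lengthen `recovery_s`.")
  ies <- merge_intervals(bind_rows(as_intervals(bolus_ies), as_intervals(spontaneous_ies)))
  if (nrow(ies) > 0 && (min(ies$start) < 0 || max(ies$end) > recovery_start))
    abort("Planted IES intervals must lie inside induction or maintenance.")
  art <- artifact_bursts
  if (!is.null(art)) {
    art <- as_tibble(art)
    if (!"gain" %in% names(art)) art$gain <- rep(10, nrow(art))
  } else art <- tibble(start = numeric(), end = numeric(), gain = numeric())
  structure(list(
    fs = fs,
    plan = list(
      induction = c(0, induction_s),
      maintenance = c(induction_s, recovery_start),
      recovery = c(recovery_start, duration),
      recovery_start = recovery_start,
      duration = duration,
      extubation_time = recovery_start + extubation_delay_min * 60,
      bolus_ies = as_intervals(bolus_ies),
      spontaneous_ies = as_intervals(spontaneous_ies),
      ies = ies,
      alpha_suppressions = as_intervals(alpha_suppressions),
      artifact_bursts = art
    ),
    band = list(
      delta_amp_uv = delta_amp_uv, alpha_amp_uv = alpha_amp_uv,
      delta_freq_hz = delta_freq_hz, alpha_freq_hz = alpha_freq_hz,
      delta_floor = delta_floor, alpha_floor = alpha_floor,
      c_delta = c_delta, c_alpha = c_alpha,
      true_t_in = t_in, true_t_out = t_out,
      true_dt_roc_min = dt_roc_min, true_df_roc_hz = df_roc_hz,
      em_frac = em_frac, freq_wander_sd_hz = freq_wander_sd_hz,
      awake_amp_uv = awake_amp_uv
    ),
    noise = list(rms_uv = noise_rms_uv, exponent = noise_exponent,
                 ies_floor_rms_uv = ies_floor_rms_uv),
    channel_gain_sd = channel_gain_sd
  ), class = "eeg_synth_spec")
}

#' Synthesize one annotated EEG record
#'
#' @param spec an [synth_spec()] object.
#' @param seed integer seed; the same seed reproduces the record exactly.
#' @return An [eeg_record()] whose `annotations` carry the phase plan, the
#'   planted interval sets and the true emergence markers.
#' @export
synthesize_record <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "eeg_synth_spec"))
  with_seed_local(seed, {
    fs <- spec$fs
    n <- as.integer(round(spec$plan$duration * fs))
    times <- (seq_len(n) - 1) / fs
    b <- spec$band

    # logistic decays of band POWER during recovery, centred so the 5 %
    # remaining-amplitude crossing equals the true marker
    t0_d <- b$true_t_in - log(1 / 0.05 - 1) / b$c_delta
    t0_a <- b$true_t_out - log(1 / 0.05 - 1) / b$c_alpha
    L_d <- 1 / (1 + exp(pmin(50, b$c_delta * (times - t0_d))))
    L_a <- 1 / (1 + exp(pmin(50, b$c_alpha * (times - t0_a))))

    onset <- 1 / (1 + exp(-(times - 60) / 15))   # induction ramp-up

    amp_d <- b$delta_amp_uv * onset *
      sqrt((L_d + b$delta_floor) / (1 + b$delta_floor))
    # alpha core: stays inside [8,12]; its band power follows the exact
    # logistic decay, so the planted t_out is the 5 % crossing of what the
    # pipeline actually fits
    amp_a <- b$alpha_amp_uv * onset *
      sqrt((L_a + b$alpha_floor) / (1 + b$alpha_floor))
    # emergence tone: ramps f0 -> f0 + df between t_in and t_out and carries
    # the peak frequency once the core has decayed (power ~ (1 - L)^2)
    amp_e <- b$alpha_amp_uv * b$em_frac * (1 - L_a)
    # awake activity (posterior alpha + beta), fading at loss of consciousness
    amp_w <- b$awake_amp_uv * (1 - onset)

    ramp <- pmin(pmax((times - b$true_t_in) /
                        (b$true_t_out - b$true_t_in), 0), 1) * b$true_df_roc_hz
    f_a <- pmin(pmax(b$alpha_freq_hz +
                       slow_wander(n, fs, b$freq_wander_sd_hz), 8.2), 11.8)
    f_e <- b$alpha_freq_hz + ramp
    f_d <- pmin(pmax(b$delta_freq_hz +
                       slow_wander(n, fs, 0.75 * b$freq_wander_sd_hz), 0.5), 3.8)

    osc_d <- amp_d * sin(2 * pi * cumsum(f_d) / fs + runif(1, 0, 2 * pi))
    osc_a <- amp_a * sin(2 * pi * cumsum(f_a) / fs + runif(1, 0, 2 * pi))
    osc_e <- amp_e * sin(2 * pi * cumsum(f_e) / fs + runif(1, 0, 2 * pi))
    osc_w <- amp_w * (0.7 * sin(2 * pi * 19 * times + runif(1, 0, 2 * pi)) +
                        0.7 * sin(2 * pi * 10.5 * times + runif(1, 0, 2 * pi)))

    gate_ies <- raised_cosine_gate(times, spec$plan$ies, edge_s = 0.2)
    gate_as <- raised_cosine_gate(times, spec$plan$alpha_suppressions,
                                  edge_s = 0.2)
    osc <- (osc_d + osc_w) * gate_ies + (osc_a + osc_e) * gate_ies * gate_as

    floor_ratio <- if (spec$noise$rms_uv > 0)
      spec$noise$ies_floor_rms_uv / spec$noise$rms_uv else 0
    noise_gate <- gate_ies + (1 - gate_ies) * floor_ratio

    channels <- c("F7", "Fp1", "Fp2", "F8")
    gains <- 1 + rnorm(4, 0, spec$channel_gain_sd)
    samples <- matrix(0, nrow = 4, ncol = n)
    art <- spec$plan$artifact_bursts
    # artifact bursts scale with the ongoing-EEG amplitude, not the noise
    # floor: motion artifacts dwarf the cortical signal
    sig_rms <- sqrt(mean(osc^2) + spec$noise$rms_uv^2)
    for (ch in 1:4) {
      noise <- colored_noise(n, fs, spec$noise$rms_uv,
                             spec$noise$exponent) * noise_gate
      x <- gains[ch] * osc + noise
      for (i in seq_len(nrow(art))) {
        idx <- which(times >= art$start[i] & times < art$end[i])
        if (length(idx) > 0) {
          edge <- 0.5 * (1 - cos(2 * pi * seq_along(idx) / length(idx)))
          x[idx] <- x[idx] +
            rnorm(length(idx), 0, art$gain[i] * sig_rms) * edge
        }
      }
      samples[ch, ] <- x
    }

    eeg_record(samples, fs = fs, channels = channels,
               annotations = list(plan = spec$plan, band = b, spec = spec))
  })
}

#' Parameter priors for a synthetic cohort
#'
#' Independent per-patient priors whose medians sit at the cohort medians a
#' pediatric or adult anesthesia cohort would show: emergence duration shift
#' centred at 7.8 min (children) / 7.3 min (adults), frequency shift at
#' 3.3 Hz / 1.9 Hz, with log-normal spreads matching the reported
#' inter-quartile ranges. Every element is a function of `n` returning `n`
#' independent draws, so prior medians can be checked by simulation.
#'
#' @param group `"children"` or `"adults"`.
#' @return Named list of sampler functions.
#' @export
cohort_priors <- function(group = c("children", "adults")) {
  group <- match.arg(group)
  rln <- function(med, sdlog, lo, hi)
    function(n) pmin(pmax(rlnorm(n, log(med), sdlog), lo), hi)
  if (group == "children") {
    list(
      dt_roc_min = rln(7.8, 0.35, 2.5, 16),
      df_roc_hz = rln(3.3, 0.35, 0.8, 6.5),
      t_in_offset_s = function(n) runif(n, 60, 180),
      c_delta = function(n) runif(n, 0.015, 0.04),
      c_alpha = function(n) runif(n, 0.012, 0.03),
      delta_amp_uv = rln(30, 0.25, 12, 70),
      alpha_amp_uv = rln(18, 0.25, 8, 45),
      delta_freq_hz = function(n) runif(n, 1, 3),
      alpha_freq_hz = function(n) runif(n, 9, 11),
      noise_rms_uv = rln(3, 0.2, 1.5, 6),
      extubation_delay_min = rln(10, 0.3, 4, 25),
      n_bolus_ies = function(n) stats::rbinom(n, 1, 0.9),
      bolus_ies_s = rln(18, 0.6, 5, 60),
      n_spont_ies = function(n) rpois(n, 2),
      spont_ies_s = rln(20, 0.5, 5, 90),
      n_alpha_s = function(n) rpois(n, 1),
      alpha_s_s = rln(30, 0.5, 8, 120),
      n_artifacts = function(n) rpois(n, 2),
      age_yr = rln(5, 0.5, 2, 15),
      weight_kg = rln(20, 0.4, 10, 60),
      p_female = 0.48
    )
  } else {
    list(
      dt_roc_min = rln(7.3, 0.3, 2.5, 16),
      df_roc_hz = rln(1.9, 0.35, 0.5, 4.5),
      t_in_offset_s = function(n) runif(n, 60, 180),
      c_delta = function(n) runif(n, 0.015, 0.04),
      c_alpha = function(n) runif(n, 0.012, 0.03),
      delta_amp_uv = rln(30, 0.25, 12, 70),
      alpha_amp_uv = rln(18, 0.25, 8, 45),
      delta_freq_hz = function(n) runif(n, 1, 3),
      alpha_freq_hz = function(n) runif(n, 9, 11),
      noise_rms_uv = rln(3, 0.2, 1.5, 6),
      extubation_delay_min = rln(10, 0.3, 4, 25),
      n_bolus_ies = function(n) stats::rbinom(n, 1, 0.3),
      bolus_ies_s = rln(8, 0.6, 3, 40),
      n_spont_ies = function(n) rpois(n, 0.5),
      spont_ies_s = rln(12, 0.5, 4, 60),
      n_alpha_s = function(n) rpois(n, 1),
      alpha_s_s = rln(30, 0.5, 8, 120),
      n_artifacts = function(n) rpois(n, 2),
      age_yr = rln(37, 0.3, 16, 58),
      weight_kg = rln(85, 0.2, 50, 130),
      p_female = 0.67
    )
  }
}

draw_patient_spec <- function(priors, fs = 250) {
  d1 <- function(f) f(1)
  induction_s <- 600
  maintenance_s <- runif(1, 1600, 2200)
  recovery_start <- induction_s + maintenance_s

  bol <- empty_intervals()
  if (d1(priors$n_bolus_ies) > 0) {
    len <- d1(priors$bolus_ies_s)
    s <- induction_s - len - runif(1, 10, 60)
    bol <- tibble(start = max(s, 30), end = max(s, 30) + len)
  }
  spont <- empty_intervals()
  k <- d1(priors$n_spont_ies)
  if (k > 0) {
    lens <- priors$spont_ies_s(k)
    starts <- sort(runif(k, induction_s + 60, recovery_start - 150))
    spont <- merge_intervals(tibble(start = starts, end = pmin(starts + lens, recovery_start - 60)))
    # suppression events are distinct episodes: enforce >= 15 s separation
    keep <- rep(TRUE, nrow(spont))
    last_end <- if (nrow(bol) > 0) bol$end[1] else -Inf
    for (i in seq_len(nrow(spont))) {
      if (spont$start[i] < last_end + 15) keep[i] <- FALSE
      else last_end <- spont$end[i]
    }
    spont <- spont[keep, ]
  }
  asup <- empty_intervals()
  k <- d1(priors$n_alpha_s)
  if (k > 0) {
    lens <- priors$alpha_s_s(k)
    starts <- sort(runif(k, induction_s + 60, recovery_start - 200))
    asup <- merge_intervals(tibble(start = starts, end = pmin(starts + lens, recovery_start - 60)))
  }
  # keep planted alpha suppressions clear of planted IES
  if (nrow(asup) > 0 && nrow(merge_intervals(bind_rows(bol, spont))) > 0) {
    ies_all <- merge_intervals(bind_rows(bol, spont))
    keep <- vapply(seq_len(nrow(asup)), function(i) {
      !any(asup$start[i] < ies_all$end + 5 & asup$end[i] > ies_all$start - 5)
    }, logical(1))
    asup <- asup[keep, ]
  }
  art <- empty_intervals()
  k <- d1(priors$n_artifacts)
  if (k > 0) {
    lens <- runif(k, 1, 5)
    starts <- sort(runif(k, 30, recovery_start + 600))
    art <- tibble(start = starts, end = starts + lens, gain = runif(k, 5, 20))
    # a burst inside a planted suppression would contradict the planted flat
    # epoch; keep artifacts clear of the suppression plan
    supp <- merge_intervals(bind_rows(bol, spont, asup))
    if (nrow(supp) > 0) {
      keep <- vapply(seq_len(nrow(art)), function(i) {
        !any(art$start[i] < supp$end + 5 & art$end[i] > supp$start - 5)
      }, logical(1))
      art <- art[keep, ]
    }
  }

  synth_spec(
    fs = fs,
    induction_s = induction_s,
    maintenance_s = maintenance_s,
    recovery_s = 1200,
    extubation_delay_min = d1(priors$extubation_delay_min),
    delta_amp_uv = d1(priors$delta_amp_uv),
    alpha_amp_uv = d1(priors$alpha_amp_uv),
    delta_freq_hz = d1(priors$delta_freq_hz),
    alpha_freq_hz = d1(priors$alpha_freq_hz),
    c_delta = d1(priors$c_delta),
    c_alpha = d1(priors$c_alpha),
    t_in_offset_s = d1(priors$t_in_offset_s),
    dt_roc_min = d1(priors$dt_roc_min),
    df_roc_hz = d1(priors$df_roc_hz),
    noise_rms_uv = d1(priors$noise_rms_uv),
    bolus_ies = bol,
    spontaneous_ies = spont,
    alpha_suppressions = asup,
    artifact_bursts = art
  )
}

true_features <- function(spec) {
  pl <- spec$plan; b <- spec$band
  indmaint <- c(0, pl$recovery_start)
  ies <- clip_intervals(pl$ies, indmaint)
  tibble(
    s_ies_true_min = sum(interval_durations(ies)) / 60,
    l_ies_true_min = if (nrow(pl$bolus_ies) > 0)
      max(interval_durations(clip_intervals(pl$bolus_ies, pl$induction))) / 60 else 0,
    dt_roc_true_min = b$true_dt_roc_min,
    df_roc_true_hz = b$true_df_roc_hz,
    t_in_true_s = b$true_t_in,
    t_out_true_s = b$true_t_out,
    extubation_delay_true_min = (pl$extubation_time - pl$recovery_start) / 60,
    alpha_amp_uv = b$alpha_amp_uv,
    delta_amp_uv = b$delta_amp_uv
  )
}

#' Synthesize a cohort with ground truth
#'
#' Draws per-patient parameters independently from the group priors and
#' returns the true value of every feature the pipeline later estimates.
#' Record synthesis can be deferred (`records = FALSE`) when only the truth
#' table or the specs are needed; `record_for_patient()` then materializes an
#' individual record reproducibly.
#'
#' @param n_patients number of patients (>= 1).
#' @param group `"children"` or `"adults"`.
#' @param seed integer master seed; drives both the parameter draws and the
#'   per-patient signal synthesis.
#' @param priors prior list as from [cohort_priors()].
#' @param records synthesize the signal arrays now?
#' @param fs sampling rate (Hz).
#'
#' @return A list with `truth` (tibble, one row per patient), `specs`,
#'   `seeds`, and `records` (list of [eeg_record()] or `NULL`).
#' @export
synthesize_cohort <- function(n_patients, group = "children", seed = 1,
                              priors = cohort_priors(group), records = TRUE,
                              fs = 250) {
  if (n_patients < 1) abort("`n_patients` must be >= 1.")
  if (length(priors) == 0) abort("`priors` must be a non-empty list.")
  out <- with_seed_local(seed, {
    specs <- vector("list", n_patients)
    demo <- vector("list", n_patients)
    for (i in seq_len(n_patients)) {
      specs[[i]] <- draw_patient_spec(priors, fs = fs)
      demo[[i]] <- tibble(
        age = priors$age_yr(1),
        gender = stats::rbinom(1, 1, priors$p_female),
        weight = priors$weight_kg(1)
      )
    }
    seeds <- sample.int(.Machine$integer.max - 1, n_patients)
    list(specs = specs, demo = bind_rows(demo), seeds = seeds)
  })
  truth <- bind_rows(lapply(out$specs, true_features)) %>%
    mutate(patient_id = sprintf("%s_%03d", group, row_number()),
           .before = 1) %>%
    bind_cols(out$demo)
  recs <- NULL
  if (records)
    recs <- purrr::map2(out$specs, out$seeds, synthesize_record)
  list(truth = truth, specs = out$specs, seeds = out$seeds, records = recs,
       group = group)
}

#' Materialize one patient's record from a deferred cohort
#' @param cohort result of [synthesize_cohort()].
#' @param i patient index.
#' @return An [eeg_record()].
#' @export
record_for_patient <- function(cohort, i)
  synthesize_record(cohort$specs[[i]], cohort$seeds[[i]])

#' Analytic band energy of a synthetic spec during maintenance
#'
#' Mean signal power (microvolts squared) expected in a frequency band during
#' the maintenance plateau, from the generator's own parameters: each tone
#' contributes amplitude^2 / 2 inside the band holding its peak, and the 1/f
#' noise contributes its closed-form band integral. Used as the independent
#' energy-accounting oracle for the spectral estimates.
#'
#' @param spec an [synth_spec()].
#' @param band numeric length-2 frequency band (Hz).
#' @return Power in microvolts squared.
#' @export
synth_band_energy <- function(spec, band) {
  b <- spec$band
  p <- 0
  if (b$delta_freq_hz >= band[1] && b$delta_freq_hz <= band[2])
    p <- p + b$delta_amp_uv^2 / 2
  if (b$alpha_freq_hz >= band[1] && b$alpha_freq_hz <= band[2])
    p <- p + b$alpha_amp_uv^2 / 2
  f1 <- max(band[1], 0.1)
  if (band[2] > f1)
    p <- p + spec$noise$rms_uv^2 *
      colored_band_fraction(c(f1, band[2]), spec$fs, spec$noise$exponent)
  p
}
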