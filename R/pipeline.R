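# End-to-end orchestration: preprocess -> spectral -> suppression ->
# emergence -> variation per patient, cohort feature assembly, and the
# Bayesian correlation battery with Table-style reports.

#' Extract every per-patient feature from one record
#'
#' Runs artifact correction, the weighted spectrogram, suppression
#' segmentation, the maintenance band statistics, the total-variation
#' statistics and the emergence markers, on the phase windows each feature
#' belongs to: total IES time over induction + maintenance, longest (bolus)
#' IES over induction, relative band-power means and total variations over
#' maintenance, sigmoid fits over the final 20 min. A failing stage flags
#' the patient and leaves its features `NA`; the rest are retained.
#'
#' @param record an [eeg_record()].
#' @param events phase boundaries: list with `induction_end`,
#'   `recovery_start` and optionally `extubation_time` (s). Default: taken
#'   from the record's annotations.
#' @param patient_id identifier copied into the output row.
#' @param emergence_window_min sigmoid fit window before the end (min).
#' @param keep_intermediates attach the suppression segmentation and
#'   emergence fits as an `"intermediates"` attribute?
#' @return One-row tibble of class `patient_features`.
#' @export
run_patient <- function(record, events = NULL, patient_id = "patient",
                        emergence_window_min = 20,
                        keep_intermediates = FALSE) {
  if (is.null(events)) {
    pl <- record$annotations$plan
    if (is.null(pl)) abort("`events` must be supplied for unannotated records.")
    events <- list(induction_end = pl$induction[2],
                   recovery_start = pl$recovery_start,
                   extubation_time = pl$extubation_time)
  }
  dur <- record_duration(record)
  induction <- c(0, events$induction_end)
  maintenance <- c(events$induction_end, events$recovery_start)
  flags <- character(0)

  rec <- tryCatch({
    mask <- detect_artifacts(record)
    if (nrow(mask$flagged) > 0) wqn_correct(record, mask) else record
  }, error = function(e) {
    flags <<- c(flags, "preprocess_failed"); record
  })

  spg <- spectrogram(rec)

  seg <- tryCatch(segment_suppressions(rec), error = function(e) {
    flags <<- c(flags, "suppression_failed"); NULL
  })
  s_ies <- l_ies <- NA_real_
  excl_alpha <- excl_delta <- empty_intervals()
  if (!is.null(seg)) {
    s_ies <- suppression_stats(seg, c(0, events$recovery_start))$s_ies_min
    l_ies <- suppression_stats(seg, induction)$l_ies_min
    excl_delta <- seg$ies
    excl_alpha <- merge_intervals(bind_rows(seg$ies, seg$alpha_s))
  }

  mean_p_alpha <- mean_band_power(relative_band_power(spg, c(8, 12)), maintenance)
  mean_p_delta <- mean_band_power(relative_band_power(spg, c(0.1, 4)), maintenance)

  v_of <- function(band, excl) {
    tr <- sg_smooth(peak_frequency(spg, band, excl))
    segs <- complement_intervals(excl, maintenance)
    total_variation(tr, segs)$value_hz_per_min
  }
  v_alpha <- tryCatch(v_of(c(8, 12), excl_alpha),
                      error = function(e) { flags <<- c(flags, "v_alpha_failed"); NA_real_ })
  v_delta <- tryCatch(v_of(c(0.1, 4), excl_delta),
                      error = function(e) { flags <<- c(flags, "v_delta_failed"); NA_real_ })

  fit_d <- fit_a <- NULL
  empty_mk <- tibble(t_in_s = NA_real_, t_out_s = NA_real_,
                     dt_roc_min = NA_real_, df_roc_hz = NA_real_,
                     fmax_in_hz = NA_real_, fmax_out_hz = NA_real_,
                     flag = NA_character_)
  if (events$recovery_start >= dur - 60) {
    # no usable recovery data: the emergence markers are undefined
    flags <- c(flags, "missing_recovery")
    mk <- empty_mk
  } else {
  mk <- tryCatch({
    fit_d <- fit_sigmoid(band_power(spg, c(0.1, 4)),
                         window = c(dur - emergence_window_min * 60, dur))
    fit_a <- fit_sigmoid(band_power(spg, c(8, 12)),
                         window = c(dur - emergence_window_min * 60, dur))
    fmax <- peak_frequency(spg, c(8, 30))
    emergence_markers(fit_d, fit_a, fmax)
  }, error = function(e) {
    flags <<- c(flags, "emergence_failed")
    empty_mk
  })
  }
  if (!is.na(mk$flag[1])) flags <- c(flags, mk$flag[1])

  extub <- if (!is.null(events$extubation_time) && !is.na(events$extubation_time))
    (events$extubation_time - events$recovery_start) / 60 else NA_real_

  out <- tibble(
    patient_id = patient_id,
    s_ies_min = s_ies, l_ies_min = l_ies,
    mean_p_alpha_pct = mean_p_alpha, mean_p_delta_pct = mean_p_delta,
    v_alpha_hz_per_min = v_alpha, v_delta_hz_per_min = v_delta,
    t_in_s = mk$t_in_s, t_out_s = mk$t_out_s,
    dt_roc_min = mk$dt_roc_min, df_roc_hz = mk$df_roc_hz,
    extubation_delay_min = extub,
    flags = paste(flags, collapse = ";")
  )
  class(out) <- c("patient_features", class(out))
  if (keep_intermediates)
    attr(out, "intermediates") <- list(segments = seg, delta_fit = fit_d,
                                       alpha_fit = fit_a)
  out
}

default_measures <- c("s_ies_min", "l_ies_min", "mean_p_alpha_pct",
                      "v_alpha_hz_per_min", "mean_p_delta_pct",
                      "v_delta_hz_per_min")

#' Pearson + Bayes-factor battery over a feature table
#'
#' For each measure/target pair: Pearson r, exact two-sided p-value, BF01
#' under the Zellner-Siow prior and its Jeffreys label; optionally the
#' partial version controlling for covariate columns.
#'
#' @param features feature table (one row per patient).
#' @param targets target column names (e.g. the emergence markers).
#' @param measures measure column names.
#' @param covariates optional covariate column names; when given, partial
#'   correlations and nested-model Bayes factors are reported instead.
#' @return Tidy tibble: `measure`, `target`, `r`, `n`, `p_value`, `bf01`,
#'   `evidence`, `kind`.
#' @export
correlation_battery <- function(features,
                                targets = c("dt_roc_min", "df_roc_hz"),
                                measures = default_measures,
                                covariates = NULL) {
  combos <- tidyr::expand_grid(measure = measures, target = targets)
  purrr::pmap(combos, function(measure, target) {
    x <- features[[measure]]; y <- features[[target]]
    if (is.null(covariates)) {
      ct <- pearson_cor(x, y)
      bf <- bf01_correlation(ct$r, ct$n)
      tibble(measure = measure, target = target, r = ct$r, n = ct$n,
             p_value = ct$p_value, bf01 = bf,
             evidence = jeffreys_label(bf), kind = "simple")
    } else {
      z <- features[, covariates]
      ct <- partial_correlation(x, y, z)
      bf <- bf01_given_covariates(x, y, z)
      tibble(measure = measure, target = target, r = ct$r, n = ct$n,
             p_value = ct$p_value, bf01 = bf,
             evidence = jeffreys_label(bf), kind = "partial")
    }
  }) %>% bind_rows()
}

#' Run the full cohort analysis
#'
#' Assembles per-patient features (running [run_patient()] where records are
#' supplied), then computes the correlation battery against the emergence
#' markers, the partial battery controlling for age/gender/weight when those
#' columns are present, the extubation-delay correlations, the
#' median/quartile summary, and the conditional probabilities of a long
#' emergence after long suppression at the 70th-percentile thresholds.
#'
#' @param x a [synthesize_cohort()] result, a list of [eeg_record()]s, or a
#'   ready feature table.
#' @param events per-patient events list (parallel to the records), if the
#'   records carry no annotations.
#' @param covariates covariate columns for the partial battery.
#' @param min_complete minimum number of patients with complete features.
#' @return Object of class `cohort_report`: `features`, `summary`, `simple`,
#'   `partial`, `extubation`, `conditional`.
#' @export
run_cohort <- function(x, events = NULL,
                       covariates = c("age", "gender", "weight"),
                       min_complete = 4) {
  if (is.data.frame(x)) {
    features <- as_tibble(x)
  } else if (is.list(x) && !is.null(x$specs)) {
    n <- nrow(x$truth)
    features <- purrr::map(seq_len(n), function(i) {
      rec <- if (!is.null(x$records)) x$records[[i]] else record_for_patient(x, i)
      run_patient(rec, patient_id = x$truth$patient_id[i])
    }) %>% bind_rows()
    features <- dplyr::left_join(
      features,
      select(x$truth, "patient_id", dplyr::any_of(c("age", "gender", "weight"))),
      by = "patient_id")
  } else {
    features <- purrr::imap(x, function(rec, i) {
      run_patient(rec, events = if (is.null(events)) NULL else events[[i]],
                  patient_id = sprintf("patient_%03d", i))
    }) %>% bind_rows()
  }

  meas <- intersect(default_measures, names(features))
  complete <- stats::complete.cases(
    features[, c(meas, "dt_roc_min", "df_roc_hz")])
  if (sum(complete) < min_complete)
    abort(sprintf("Only %d patients with complete features (need >= %d).",
                  sum(complete), min_complete))
  feat <- features[complete, ]

  summary_tbl <- feat %>%
    select(all_of(c("dt_roc_min", "df_roc_hz", meas))) %>%
    tidyr::pivot_longer(dplyr::everything(), names_to = "measure") %>%
    group_by(.data$measure) %>%
    summarise(median = median(.data$value, na.rm = TRUE),
              q1 = quantile(.data$value, 0.25, na.rm = TRUE, names = FALSE),
              q3 = quantile(.data$value, 0.75, na.rm = TRUE, names = FALSE),
              .groups = "drop")

  simple <- correlation_battery(feat, measures = meas)
  covs <- intersect(covariates, names(feat))
  partial <- if (length(covs) > 0 && nrow(feat) >= length(covs) + 5)
    correlation_battery(feat, measures = meas, covariates = covs) else NULL
  extubation <- if (!all(is.na(feat$extubation_delay_min)))
    correlation_battery(feat, targets = "extubation_delay_min",
                        measures = meas) else NULL

  conditional <- bind_rows(
    mutate(conditional_probability(feat, "s_ies_min", "dt_roc_min"),
           what = "P(dt_roc > q70 | s_ies > q70)"),
    if (any(feat$l_ies_min > 0, na.rm = TRUE))
      mutate(conditional_probability(feat, "l_ies_min", "s_ies_min",
                                     condition_value = 0.5),
             what = "P(s_ies > q70 | l_ies > 0.5 min)")
  )

  structure(list(features = features, summary = summary_tbl,
                 simple = simple, partial = partial,
                 extubation = extubation, conditional = conditional),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> %d patients\n", nrow(x$features)))
  cat("\nMedians [Q1, Q3]:\n"); print(x$summary)
  cat("\nSimple correlations vs emergence markers:\n")
  print(x$simple, n = Inf)
  invisible(x)
}

#' Write a cohort report to CSV files
#' @param report a [run_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(report$features, file.path(dir, "features.csv"), row.names = FALSE)
  utils::write.csv(report$summary, file.path(dir, "summary.csv"), row.names = FALSE)
  utils::write.csv(report$simple, file.path(dir, "correlations.csv"), row.names = FALSE)
  if (!is.null(report$partial))
    utils::write.csv(report$partial, file.path(dir, "partial_correlations.csv"), row.names = FALSE)
  if (!is.null(report$extubation))
    utils::write.csv(report$extubation, file.path(dir, "extubation_correlations.csv"), row.names = FALSE)
  utils::write.csv(report$conditional, file.path(dir, "conditional_probabilities.csv"), row.names = FALSE)
  invisible(dir)
}
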