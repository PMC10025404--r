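# gaeeg — spectral EEG analysis of the phases of general anesthesia

`gaeeg` quantifies frontal EEG (electrodes F7, Fp1, Fp2, F8) recorded
through the three phases of general anesthesia — induction, maintenance,
recovery — and asks whether what happens early in anesthesia anticipates the
recovery. It is aimed at researchers in anesthesia neuromonitoring and at
anyone who needs a tested, reusable implementation of this analysis family.

The pipeline computes, per patient:

* **Artifact correction** — sliding-window power/MAD flagging and wavelet
  quantile normalization (WQN) of flagged segments;
* **Weighted spectrogram** — 20 s Hann windows, 75 % overlap, channel mean
  `P_av = (0.5 P_F7 + P_Fp1 + P_Fp2 + 0.5 P_F8)/3`;
* **Suppression segmentation** — iso-electric suppressions (IES) and
  α-suppressions (αS) from the dual-envelope rule with thresholds
  `T_IES = min(8 µV, median D)` and `T_α = min(0.25, median D_α)`, opened
  with a 0.5 s structuring element; totals `S_IES`, `L_IES` in minutes;
* **Band statistics** — absolute and relative δ (0.1–4 Hz) and α (8–12 Hz)
  band powers; maintenance means `P̄_δ`, `P̄_α` (%);
* **Emergence markers** — sigmoid fits `a/(1+e^{c(t−t₀)})+b` of the band
  powers over the final 20 min; `t_in` (δ crossing at 5 % remaining
  amplitude), `t_out` (α crossing), the duration shift
  `Δt_ROC = (t_out − t_in)/60` min and frequency shift
  `Δf_ROC = f_max(t_out) − f_max(t_in)` Hz of the α-band emergence
  trajectory;
* **Instability** — total variation `V_α`, `V_δ` (Hz/min) of the
  Savitzky–Golay-smoothed peak-frequency tracks over suppression-free
  segments;

and, per cohort, a Bayesian correlation battery: Pearson and partial
correlations with exact t-transform p-values and Zellner–Siow g-prior Bayes
factors

```
BF10 = sqrt(n/2)/Γ(1/2) ∫₀^∞ (1+g)^((n−p−1)/2) (1+(1−r²)g)^(−(n−1)/2)
                              g^(−3/2) e^(−n/(2g)) dg,     BF01 = 1/BF10,
```

with Jeffreys evidence labels (BF01 1–3 anecdotal, 3–10 moderate, 10–30
strong, 30–100 very strong, >100 decisive support for no correlation).

Because no public recordings accompany this analysis family, the package
ships a calibrated synthetic cohort generator (`synth_spec()`,
`synthesize_record()`, `synthesize_cohort()`) that plants IES/αS epochs,
motion artifacts, and an emergence trajectory with known markers, and
returns the ground truth of every feature the pipeline estimates — the test
suite validates every stage against it.

## Worked example

Synthesize one pediatric patient (60 min, 250 Hz) with a bolus-induced
40 s IES at the end of induction and a 60 s α-suppression during
maintenance, then extract all features:

```r
library(gaeeg)

spec <- synth_spec(
  bolus_ies = data.frame(start = 520, end = 560),
  alpha_suppressions = data.frame(start = 1100, end = 1160)
)
rec <- synthesize_record(spec, seed = 42)
rec
#> <eeg_record> 4 channels (F7, Fp1, Fp2, F8), 3600.0 s @ 250 Hz, annotated

features <- run_patient(rec, patient_id = "demo")
round(as.data.frame(features[, 2:12]), 2)
#>   s_ies_min l_ies_min mean_p_alpha_pct mean_p_delta_pct v_alpha_hz_per_min
#> 1      0.66      0.66            25.78            74.19               0.17
#>   v_delta_hz_per_min  t_in_s t_out_s dt_roc_min df_roc_hz extubation_delay_min
#> 1               0.11 2521.88 2987.12       7.75      3.55                   10
```

Reading the row: the pipeline found 0.66 min of iso-electric suppression
(the planted 40 s bolus IES; true total 0.67 min), a maintenance relative α
power of 26 %, and an emergence trajectory lasting 7.75 min with a 3.55 Hz
upward frequency shift — against planted true values of 7.8 min and 3.3 Hz.

The Bayesian battery turns a correlation coefficient and a sample size into
evidence for or against the null:

```r
bf01_correlation(r = -0.44, n = 27)   # 0.49 — anecdotal evidence for H1
bf01_correlation(r =  0.04, n = 27)   # 6.61 — moderate evidence for H0
```

Cohorts run end to end:

```r
cohort <- synthesize_cohort(12, group = "children", seed = 7)
report <- run_cohort(cohort)
report$simple          # r, p, BF01, Jeffreys label per measure x marker
write_cohort_report(report, "report/")
```

`autoplot()` methods cover the spectrogram, band-power series,
peak-frequency tracks, sigmoid fits and the suppression segmentation;
`tidy()`/`glance()` summarize fitted sigmoids. The methods vignette
(`vignettes/gaeeg-methods.Rmd`) documents the model, every tunable
parameter, and the generator's calibration.

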