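# patrec

Cuff-less blood-pressure **trend** analysis from synchronized ECG and PPG,
built around beat-by-beat **Pulse Arrival Time** (PAT): the delay between
the ECG R-peak and the steepest upstroke (maximum first derivative) of the
photoplethysmogram. Because PAT shortens as systolic pressure rises,
normalized PAT excursions can track SBP trends between intermittent cuff
readings.

The package implements a complete, tested pipeline for an
intermittent-cuff validation protocol — per subject, two sessions (rest /
post-exercise) of 11 × 10 s synchronized 1 kHz cycles, with oscillometric
cuff readings after cycles 1, 4, 7 and 10:

* **Extraction** — 50 Hz notch + 3rd-order Butterworth band-pass (0.5–40 Hz
  ECG, 0.5–10 Hz PPG), all zero-phase; Pan-Tompkins R-peak detection; PPG
  maximum-slope fiducials; per-cycle median PAT with a rolling 3-point
  outlier rule.
* **Recovery modelling** — post-exercise PAT fitted by
  `PAT(x) = PAT∞ + ΔPAT·e^(−k(x−1))` (bounded nonlinear least squares)
  against linear and logarithmic alternatives, ranked by R².
* **Recovery Index** — range-based normalization mapping the maximal
  perturbation to −100 % and the baseline-session average to 0 %, computed
  for PAT and for cuff SBP (the sparse 4-point SBP series is oversampled to
  the 11-cycle grid through the same mono-exponential shape).
* **Agreement statistics** — Shapiro-Wilk / Kruskal-Wallis /
  Mann-Whitney-with-Bonferroni across REST / EXERCISE / RECOVERY phases;
  subject-wise Pearson correlation with |z| > 2 cohort screening;
  Bland-Altman bias and limits of agreement; Lin's concordance correlation
  coefficient.
* **Synthetic campaigns** — a generator that reproduces the acquisition
  protocol with exact ground-truth fiducials (analytically placed
  raised-cosine PPG upstrokes), inverse PAT–SBP coupling, powerline and
  motion noise, and optional artifact injection, used throughout the test
  suite since no subject recordings are distributed.

See `vignettes/patrec-methods.Rmd` for the full model description, design
decisions and limitations.

## Worked example

```r
library(patrec)

camp <- generate_campaign(n_subjects = 19, seed = 1)
camp
#> <pat_campaign>
#>   subjects: 19  cycles: 418  cuff readings: 152
#>   schedule: 2 sessions x 11 cycles x 10 s @ 1 kHz; 30 s cycle slot
#>   seed: 1

summaries <- extract_cycles(camp)       # beat detection -> per-cycle medians + QC
analysis  <- analyze_summaries(summaries, camp$readings)
analysis
#> <pat_analysis>
#> cycles: 418  missing medians: 0  outlier-flagged: 34
#> aggregate recovery ranking: mono_exp > log > linear (best R^2 = 0.9991)
#> subject-wise Pearson r: mean 0.991 sd 0.0087 (18/19 retained)
#> Bland-Altman bias 1.1  LoA [ -9.035 , 11.23 ]  CCC 0.985
```

Reading the output: of 418 acquisition windows, 34 cycle medians were
rejected by quality control; the aggregate post-exercise PAT trajectory is
best described by the mono-exponential recovery model; after excluding one
cohort outlier by the z-score screen, every retained subject's PAT
Recovery Index tracks the (oversampled) SBP Recovery Index with r ≈ 0.99;
the pooled Bland-Altman bias of ~1.1 percentage points with limits of
agreement of roughly ±10 points and a concordance coefficient of 0.985
says the two normalized recovery trajectories are interchangeable up to
modest subject-specific spread.

Individual stages are ordinary functions over tibbles and compose with the
pipe; fitted objects support `tidy()`, `glance()` and `autoplot()`:

```r
fit <- fit_recovery_model(1:11, 250 - 60 * exp(-0.4 * (0:10)), "mono_exp")
glance(fit)
#> # A tibble: 1 × 5
#>   model    r_squared n_points n_params converged
#>   <chr>        <dbl>    <int>    <int> <lgl>
#> 1 mono_exp         1       11        3 TRUE
autoplot(fit)
```

File-based runs (one CSV per cycle, `t_s,ecg,ppg`; cuff readings CSV; JSON
manifest) go through `write_campaign()` / `read_campaign()` /
`run_pipeline()`, which persists every intermediate
(`summaries.csv`, `ri_series.csv`, `fits.json`, `agreement.json`,
`log.json`) plus the seed and configuration.

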