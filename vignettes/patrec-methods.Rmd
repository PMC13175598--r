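---
title: "Methods: PAT-based blood-pressure trend analysis in patrec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PAT-based blood-pressure trend analysis in patrec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patrec)
```

## The physiological problem

Pulse Arrival Time (PAT) is the delay between the electrical activation of
the heart (the ECG R-peak) and the arrival of the resulting pressure pulse
at a peripheral site, observed optically as the steepest upstroke of the
photoplethysmogram (PPG). PAT shortens when systolic blood pressure (SBP)
rises, so relative PAT excursions can track SBP *trends* without a cuff.
`patrec` implements a complete analysis chain for an intermittent-cuff
validation protocol: each subject is recorded in two sessions (rest and
immediately after exercise) of 11 ten-second synchronized ECG+PPG cycles at
1 kHz, with oscillometric cuff readings after cycles 1, 4, 7 and 10 of each
session (one cycle occupies a 30 s slot: 10 s acquisition, 20 s transfer).

The package answers three questions: does PAT react to an exercise
perturbation the way SBP does (phase statistics); does the PAT recovery
follow first-order dynamics (model comparison); and do normalized PAT and
SBP recovery trajectories agree subject by subject (correlation,
Bland-Altman, concordance)?

It deliberately does **not** estimate absolute blood pressure: PAT contains
the pre-ejection period and depends on vascular tone, so absolute
calibration is a separate problem. All agreement claims are about
normalized trends.

## Signal processing chain

Each cycle is processed independently:

1. **Notch filter**, 50 Hz, quality factor 30 (a constrained biquad):
   removes powerline pickup.
2. **Band-pass**, 3rd-order Butterworth: 0.5–40 Hz for the ECG (isolates
   QRS energy), 0.5–10 Hz for the PPG (keeps the pulsatile band, suppresses
   motion noise).
3. **R-peak detection** with the Pan-Tompkins stages (first difference,
   squaring, 150 ms moving-window integration, adaptive dual thresholds,
   200 ms refractory, 360 ms T-wave slope rule, search-back at half
   threshold), refined to the local ECG maximum within ±25 ms.
4. **PPG fiducials**: pulse peaks by prominence (default 20 % of the
   cycle's peak-to-peak amplitude, minimum spacing 250 ms); for each beat
   the maximum-slope point between the R-peak and the first following pulse
   peak. `PAT = (md − r) / fs`.
5. **Per-cycle median** PAT over retained beats (at least 3, else the cycle
   yields no value), then **rolling-window quality control** (below).

All filtering is applied **zero-phase** (forward–backward, with
odd-reflection padding of 6 s to suppress edge transients). This matters
because the two channels pass through different bands: causal filters would
delay the PPG differently from the ECG and bias every PAT by a fixed,
band-dependent amount. Zero-phase application removes group delay entirely;
the padding keeps the 0.5 Hz high-pass edge from smearing start-up
transients into the first beats.

Per-beat PAT values outside 100–600 ms are discarded as implausible
(configurable); beats with no pulse peak before the next R-peak are dropped
with reason codes (`no_pulse`, `cycle_edge`). Beats hugging the record
edges are also dropped as `cycle_edge` (default margin 150 ms at the start,
300 ms at the end): a pulse peaking inside the final fraction of a second is
truncated mid-decay, and even zero-phase filters respond to that truncation
with a several-ms fiducial bias. On noise-free synthetic data the chain then
recovers every retained beat's PAT within 2 ms (quantization plus residual
filter asymmetry), with a median error well under 1 ms.

## Quality control: the rolling 3-point rule

For every valid cycle median, the mean and sample standard deviation
(denominator n−1) of its **two nearest other valid medians** are computed;
the point is flagged when it deviates from that local mean by strictly more
than 3 standard deviations. Two design points deserve emphasis:

* **The evaluated point is excluded from its own window.** In a 3-point
  window that includes the centre, no point can ever deviate from the
  window mean by more than 2/√3 ≈ 1.15 window standard deviations, so a
  3-sigma rule would never flag anything. Neighbour-only statistics restore
  the rule's evident intent.
* **Endpoints are never flagged.** A centred window does not exist at the
  first or last valid cycle, and judging an endpoint against its two
  one-sided successors is not outlier detection but trend extrapolation: on
  a brisk mono-exponential recovery (rate k ≳ 0.5 per cycle) the first
  post-exercise cycle *always* sits more than 3 neighbour-standard-
  deviations below cycles 2–3, and a one-sided rule would systematically
  delete the physiological extremum — destroying the −100 % anchor of the
  Recovery Index downstream. Quality control is therefore conservative at
  the boundaries.

A known statistical property of this (deliberately simple, field-standard)
rule is its heavy-tailed behaviour on serially *uncorrelated* series: with
only two neighbours the studentized deviation is Cauchy-like, and white
per-cycle noise would be flagged at ≈ 25 % regardless of amplitude. Real
median-PAT series are smooth (autonomic drift dominates beat noise after
median aggregation), which keeps the observed false-flag rate near five
percent; the synthetic generator reproduces that serial correlation (below)
rather than white cycle noise. Operators needing a stricter false-flag rate
should widen the window rather than raise the threshold.

## Recovery modelling

Post-exercise median PAT is modelled over cycle index $x = 1..11$ by three
candidates:

$$\mathrm{PAT}(x) = \mathrm{PAT}_\infty + \Delta\mathrm{PAT}\,e^{-k(x-1)},
\qquad \mathrm{PAT}(x) = a x + b, \qquad \mathrm{PAT}(x) = a + b\log x.$$

The mono-exponential is fitted by bounded Levenberg–Marquardt least squares
(`minpack.lm`), $k \in [0, 20]$, initialized from the data
($\mathrm{PAT}_\infty \leftarrow$ last point, $\Delta\mathrm{PAT}
\leftarrow$ first − last, $k \leftarrow 0.5$); the other two are closed
form. Models are ranked by $R^2 = 1 - SS_{res}/SS_{tot}$ computed on the
fitted points (no held-out data — the comparison is descriptive, not
predictive); ties favour fewer parameters, and a constant series leaves
$R^2$ undefined (reported `NA`) rather than fabricated.

**Recovery Index.** To compare PAT and SBP trends in one space, each
post-exercise series is affinely mapped so that the maximal perturbation
(PAT minimum / SBP maximum observed in the session) lands at **−100 %** and
the baseline-session average at **0 %**:

$$RI_{\mathrm{PAT}}(i) = \frac{\mathrm{PAT}(i) - \mathrm{PAT}_{\min}}
{\mathrm{PAT}_{\mathrm{baseline}} - \mathrm{PAT}_{\min}} \cdot 100 - 100.$$

The trailing −100 makes the anchors explicit: the same formula without it
would put the extremum at 0 and baseline at +100, which is the identical
affine map shifted by a constant; the −100/0 convention is used everywhere
in this package. Outlier-rejected cycles stay missing.

**SBP oversampling.** The cuff provides only 4 post-exercise readings (after
cycles 1, 4, 7, 10). Their RI values are oversampled to the 11-cycle grid
by fitting the same mono-exponential shape (asymptote + amplitude ·
$e^{-k(x-1)}$, $k \in [0,20]$) and evaluating it on 1..11. Oversampling is
done in RI space rather than raw mmHg — the two are affinely equivalent, and
RI space is where the comparison happens. Fitting 3 parameters to 4 points
is near-saturated by design; the $k$ bounds plus a flagged piecewise-linear
fallback (flat extrapolation) guard the degenerate cases.

## Agreement statistics

* **Phases**: REST = all baseline cycles; EXERCISE = post cycles 1–3;
  RECOVERY = post cycles 9–11 (post 4–8 unassigned). For BP, REST is the
  per-subject mean of the four baseline readings, EXERCISE/RECOVERY the
  first/last post reading. PAT values are baseline-centred per subject
  before pooling; BP is left absolute, because centring would make every
  REST BP value identically zero (REST *is* the subject's own baseline
  mean) and degenerate the normality tests.
* **Battery**: Shapiro–Wilk per phase; Kruskal–Wallis omnibus across the
  three phases; pairwise two-sided Mann–Whitney (normal approximation, tie
  correction) with Bonferroni adjustment over the 3 pairs, run **only**
  when the omnibus test is significant (α = 0.05) — so a flat measure such
  as DBP is never probed pairwise.
* **Subject-wise correlation**: Pearson r between aligned RI series
  (pairwise deletion of outlier-rejected cycles; p from the t distribution
  with n−2 df; at least 3 pairs). Cohort screening standardizes the r
  values (sample sd) and excludes |z| > 2 in a single pass before the
  population summary.
* **Bland-Altman** on pooled pairs of retained subjects: bias = mean of
  $D_i = RI_{\mathrm{PAT}} - RI_{\mathrm{SBP}}$, limits of agreement
  bias ± 1.96 · sample sd.
* **Concordance** (Lin): $\rho_c = 2 s_{xy} / (s_x^2 + s_y^2 +
  (\bar x - \bar y)^2)$ with moment (denominator n) estimates — the form
  that satisfies $|\rho_c| \le |r|$ exactly.

## The synthetic campaign generator

No subject-level recordings are distributed with this package, so
validation runs on synthesized campaigns with exact ground truth.

* **ECG**: per beat, five Gaussian deflections (P, Q, R, S, T; QRS width
  ≈ 20 ms, R amplitude 1). Enough morphology for Pan-Tompkins to behave
  realistically (T-wave discrimination included) without a full dynamical
  heart model.
* **PPG**: per beat, a raised-cosine upstroke of 151 samples (odd by
  construction) followed by a raised-cosine decay shortened so pulses never
  overlap. The steepest first difference of this pulse is *analytically*
  unique and placed exactly at the beat's R sample + its true PAT — the
  ground-truth fiducial is exact, not estimated.
* **Beat schedule**: first beat at a uniform phase within one RR interval
  (no phase locking across cycles), multiplicative Gaussian RR jitter
  (sd 3 %), floored at 260 ms; post-exercise heart rate decays linearly
  from `hr_post_bpm` to `hr_rest_bpm` across the 11 cycles.
* **True PAT**: baseline sessions sit at `pat_baseline_ms`; post-exercise
  cycles follow the mono-exponential recovery. On top of this, each beat
  gets i.i.d. jitter (sd 2 ms) and each session a smooth sinusoidal drift
  (amplitude 3–8 ms, period 14–22 cycles, random phase). The drift is what
  makes per-cycle medians vary *smoothly*, as real series do — slow
  vasomotor/autonomic wander dominates residual beat noise after median
  aggregation. A generator with white cycle-to-cycle noise would be both
  unphysiological and adversarial to any local-window outlier rule (see
  the quality-control section).
* **Coupling**: cuff SBP = baseline SBP + γ · (cycle mean true PAT −
  baseline PAT) + N(0, 2 mmHg), with γ drawn in −0.8…−0.4 mmHg/ms, so a
  60 ms PAT drop maps to a 24–48 mmHg systolic rise; DBP stays at baseline
  + N(0, 1.5 mmHg).
* **Artifacts** (optional, for QC evaluation): `spike_burst` (70 half-sine
  transients of 20–80 ms over an 8 s window, both channels),
  `signal_dropout` (PPG collapses to near-zero over 90 % of the cycle),
  `wander_surge` (0.9–1.6 Hz oscillation at 3× pulse amplitude over a
  flat-top window spanning 90 % of the cycle; slower wander would simply be
  erased by the 0.5 Hz high-pass edge and never reach the detectors). The
  kinds exercise
  different failure routes: corrupted fiducials, too-few beats, and
  swamped pulse prominence respectively. Their strengths were chosen so
  corruption actually perturbs (or removes) the cycle median — very large
  localized disturbances are paradoxically *less* detectable by a
  median-based summary, because the affected beats fail plausibility
  checks and drop out, leaving a clean remainder. Disturbances whose
  corrupted medians happen to land at plausible values remain undetectable
  in principle by any median-threshold rule; the shipped test-suite
  quantifies the resulting operating point.
* **Determinism**: one RNG stream per subject derived from the root seed,
  so enlarging a cohort never changes earlier subjects' data.

Default population ranges (`population_ranges()`) describe a healthy adult
cohort: baseline PAT 220–300 ms, exercise drop 40–80 ms, recovery rate
0.25–0.8 per cycle, resting HR 55–75 bpm, post-exercise HR 95–120 bpm,
baseline SBP 105–130 mmHg. These are documented defaults for a plausible
cohort, not a claim about any particular study population.

**What the generator does not emulate**: pre-ejection-period dynamics,
respiratory modulation of the PPG, arrhythmia, sensor clock drift
(synchronization is assumed perfect), or PPG morphology changes with
vascular tone. Green tests therefore demonstrate correctness of the
*pipeline* under the stated signal model, not field performance on
arbitrary wearable data.

## Numerical choices and degenerate inputs

* Sample indices are 1-based (R convention); the ground-truth contract is
  `true_md_sample == round(t·fs) + round(pat·fs/1000) + 1`.
* The maximum-slope estimate is the upper sample of the steepest first
  difference; with a 151-sample (odd) rise the true argmax is unique.
* Sample (n−1) standard deviations everywhere except the concordance
  coefficient, which uses its moment (n) definition.
* Constant series: `R²` reported `NA`; zero-spread correlation sets exclude
  nobody; zero-variance CCC and degenerate RI normalization raise errors
  rather than returning NaN.
* Mann–Whitney uses the normal approximation unconditionally, for tie
  robustness and run-to-run consistency.
* Filter padding length 3 s (or the signal length, if shorter).

## Problem sizes used by the test-suite

The shipped tests validate on: 19-subject campaigns (418 cycles) for
protocol structure and end-to-end behaviour; a 5-subject noise-free
campaign for per-beat fiducial accuracy; a 20-subject campaign with 10 %
artifact cycles for the quality-control operating point; 200 replicates per
cell of a k × ΔPAT grid for parameter recovery; and 2000 null replicates
(n = 19 per phase) for Kruskal–Wallis calibration. These sizes mirror the
protocol's natural scale while keeping the default suite comfortably
runnable on one CPU.

## Known limitations

* The rolling QC rule's false-flag rate depends on the serial correlation
  of the median series; on pathologically white series it over-flags (a
  property of the rule, not the implementation).
* The SBP oversampling model assumes the same first-order recovery shape as
  PAT; a subject whose SBP recovers non-monotonically is fitted poorly and
  shows up as a correlation outlier rather than being corrected.
* Phase statistics pool subjects; they are cohort-level statements, not
  per-subject inference.
* Absolute BP estimation is out of scope by design.
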