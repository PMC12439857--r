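---
title: "Estimating arterial CO2 from noninvasive intraoperative parameters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating arterial CO2 from noninvasive intraoperative parameters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Arterial partial pressure of CO2 (PaCO2) is the gold-standard measure of
ventilation adequacy in mechanically ventilated patients, but it requires an
arterial blood gas analysis (ABGA): an invasive, intermittent measurement.
End-tidal CO2 (ETCO2) from capnography is its continuous, noninvasive
surrogate. The PaCO2–ETCO2 gradient is commonly quoted as 3–5 mm Hg in
healthy lungs, but alveolar dead space and ventilation/perfusion mismatch
widen and destabilise it: in intraoperative cohorts the observed gradient
averages well above 5 mm Hg and spans tens of mm Hg, so neither a fixed
offset nor a single linear rescaling of ETCO2 is a reliable estimator.

`co2gap` implements, as a tested and reusable pipeline, an analysis that
estimates PaCO2 at arbitrary intraoperative time points from noninvasive
parameters only, and evaluates the estimate the way method-comparison studies
require. The pipeline has five stages, each an exported function:

1. **simulate** — `generate_cohort()`: a synthetic surgical cohort standing in
   for a real intraoperative database,
2. **align** — `align_events()`: refinement of each ABGA timestamp via
   arterial-pressure surge detection,
3. **extract** — `assemble_feature_table()`: windowed biosignal medians plus
   engineered physiological indices,
4. **train** — `run_nested_cv()`: case-grouped nested cross-validation of a
   gradient-boosted regressor against two ETCO2 baselines,
5. **evaluate** — `build_report()`: error metrics with fold confidence
   intervals, Bland–Altman agreement, ICC, clinical-utility error bands, and
   additive feature attributions.

`run_pipeline()` chains all five from a single `pipeline_config()` and one
global seed.

## Timestamp refinement from pressure surges

Database timestamps of ABGA results record when a result was *entered*, not
when blood was *drawn*; the entry lag is tens of seconds to minutes. Because a
blood draw through an arterial line transiently occludes the line (and the
patient may react), it produces a short surge in the mean arterial pressure
(MAP) trace. The detector standardises the 20 minutes of MAP preceding the
recorded timestamp against that window's own mean and sample SD, takes maximal
runs of samples with z > 3 (one-sided: draws raise MAP), and calls the period
nearest the recorded timestamp the draw; the representative time is the
period's maximum-z sample. Events with no detectable surge are excluded as
unreliably timed rather than guessed.

Design choices the detector needed that its description leaves open:

- **Reference distribution for z.** The lookback window itself. It is
  self-contained and robust to slow case-level drift; no global or per-case
  statistics leak in.
- **Representative time within a period.** The argmax of z — the pressure
  peak is the best marker of the line occlusion.
- **One-sided exceedance.** The physiological hypothesis is a pressure
  *rise*; negative excursions (e.g. zeroing artifacts) must not be mistaken
  for draws.
- **Nearest period.** Since only samples at or before the recorded timestamp
  are ever inspected (no lookahead), every candidate period precedes the
  timestamp and "nearest" reduces to "latest". Boundary distance is used, and
  an exact tie (impossible for disjoint one-sided periods, but kept as a
  guard) resolves to the later period.
- **Blackout.** The estimation time (trigger) is set 60 s before the inferred
  draw, and the 60-s observation window ends at the trigger with a blackout
  gap of 0 s by default: the pre-trigger interval already separates the
  window from the draw, and no duration for the blackout is prescribed.
  `alignment_config(blackout_s = …)` exposes it.

## Feature extraction

Within each event's observation window `[trigger − blackout − 60 s,
trigger − blackout)` (half-open), every channel is filtered in two stages and
summarised by its median:

1. **Plausibility bounds** remove physically impossible readings (SpO2 of
   250%, negative pressures). The defaults in `default_plausibility()` are
   deliberately wide — they encode impossibility, not abnormality — and are
   configuration, not fitted values.
2. **IQR rule** with k = 3 removes extreme outliers relative to the window's
   own quartiles (linear-interpolation convention). Plausibility runs first
   so that impossible values cannot distort the quartiles.

Engineered features add recognised physiological indices: tidal volume per kg
ideal body weight (Devine formula), SpO2/FiO2, PEEP/FiO2, respiratory-system
compliance `CRS = TV/(PPLAT − PEEP)` (missing when driving pressure is
non-positive), and the rapid shallow breathing index `RSBI = RR/TV(L)`.
Pulmonary function is regraded from FEV1/FVC and FVC %predicted with the
conventional 0.70 and 80% cutoffs into none/obstructive/restrictive/mixed.
Events missing any predictor are removed (listwise deletion) and logged with
the missing columns; no imputation.

## Modeling and validation

Validation is a 7-outer × 6-inner nested cross-validation **partitioned at
the surgical-case level**: all events of a case stay on one side of every
split, so patient physiology can never leak from training to test. Within
each outer fold, continuous features are robust-scaled (median/IQR) using
training rows only, a random search (default 20 trials over tree depth 3–10,
learning rate 0.01–0.3 log-uniform, 100–1000 boosting rounds, L2 1–10)
selects hyperparameters by mean MAE across the six inner validation folds,
and the winner is refit on the full outer training set. Two baselines are fit
per fold: the fixed offset `ETCO2 + 5 mm Hg` and an ordinary least-squares
regression of PaCO2 on ETCO2 alone.

The boosted backend is xgboost behind a fit/predict/attribute contract.
Factor predictors are one-hot encoded *inside* the backend: with
cardinalities of at most five the encodings are equivalent for tree models,
and numeric-only splits keep the attribution path (below) simple and exact.
`max_bin = 64` is used for histogram construction — ample resolution for
tables of a few hundred to a few thousand rows.

## Evaluation

- **Error metrics.** MAE, MSE, RMSE per outer fold (RMSE as the root of each
  fold's MSE, then averaged), summarised as mean with a Student-t 95% CI
  across folds. Subgroups (hypocapnic < 35, normocapnic 35–45, hypercapnic
  > 45 mm Hg, always by *actual* PaCO2) are computed per fold then
  CI-averaged; a fold with an empty subgroup is skipped with a warning.
- **Bland–Altman.** Differences are `predicted − actual` throughout (an
  overpredicting model has positive bias); limits of agreement are
  bias ± 1.96 sample SD of the differences.
- **ICC.** The two-way random-effects, absolute-agreement, single-measurement
  form ICC(2,1), computed from the two-way ANOVA mean squares with the
  F-based confidence interval. Absolute agreement is the variant consistent
  with using Bland–Altman alongside it: it penalises systematic offsets that
  Pearson correlation ignores. The variant label is recorded in the report.
- **Clinical utility.** |error| < 5 mm Hg highly acceptable, 5–10 inclusive
  moderately acceptable, > 10 unacceptable ("below 5" and "exceeding 10" fix
  the open/closed sides).
- **Attributions.** Exact additive (SHAP) attributions, computed out-of-fold:
  each event is attributed by the model of the fold that held it out. The
  package re-walks the dumped trees in double precision (`src/treeshap.cpp`)
  rather than using the booster's own single-precision contribution path, so
  the additivity identity `base + Σφ = model output` holds to ~1e-12 and is
  verified on every row; split comparisons are done in single precision to
  replicate the backend's leaf selection exactly, and the attributions agree
  with the backend's own to its float32 noise (~3e-6), which a test asserts.
  One-hot indicator attributions are summed back to their source feature.

## The synthetic cohort generator

No patient data ships with the package; `generate_cohort()` produces cohorts
with the statistical structure the analysis assumes, and its defaults *are*
the study conditions the package is tested under:

- **Channels.** 14 channels at 1 Hz. Physiology (MAP, HR, SpO2, BT, ETCO2,
  CO) follows mean-reverting (Ornstein–Uhlenbeck) noise around clinically
  typical means (MAP 75 ± 4 mm Hg, ETCO2 35 ± 2 mm Hg, BT 36.3 °C, SpO2 98%);
  ventilator settings (PEEP, FiO2, RR, TV) are piecewise-constant per case
  with occasional step changes; pressure channels derive from a per-case
  respiratory compliance (~N(50, 10) mL/cmH2O) plus measurement noise.
- **Bounded, two-timescale MAP noise.** MAP physiologic variation is a fast
  mean-reverting component (τ = 10 s, SD 4 mm Hg) plus a slow baseline drift
  (τ = 1 h, SD 1.5 mm Hg), both transformed to a uniform marginal of the same
  SD (max deviation √3 ≈ 1.73 SD). Bounded tails mean detector-grade
  excursions (z > 3) can come *only* from injected artifacts — a Gaussian
  marginal would cross z = 3 by chance in a 20-minute window often enough to
  contaminate the surge-free ground truth — and the short fast timescale
  gives each 20-minute window enough effective samples that its empirical SD
  concentrates near the marginal SD (a slowly mixing process would let the
  window SD dip and push bounded noise past the threshold).
- **Events.** 2–4 draws per case, separated by at least the detector lookback
  plus the surge width so one event's surge cannot fall into another event's
  window; draws every 20+ minutes during multi-hour cases are clinically
  ordinary. The pressure surge (raised-cosine bump, 20–40 mm Hg over
  10–24 s) is centred on the draw so the pressure peak marks the draw time;
  a configurable fraction (default 11.4%) of draws produce no surge.
  Off-draw distractor bumps (default 0.2/h) exercise nearest-period
  selection, and are never placed inside a surge-free event's lookback.
- **Entry delays.** Log-normal with meanlog = log(34) and sdlog = 0.665,
  giving median 34 s and quartiles ≈ 21.7/53.3 s. Only the delay's summary
  statistics are prescribed by the design; the log-normal is the simplest
  positive right-skewed family matching them.
- **Target.** PaCO2 = ETCO2 window median + gradient, with
  `gradient = g0 + g_age·(age−50)/10 − g_bt·(BT−36.5) − g_sf·(SF−400)/100 −
  g_crs·(CRS−50)/10 + N(0, σ_g)` — the simplest form with the physiologically
  expected directions (wider gradient with higher age, lower temperature,
  worse oxygenation, stiffer lungs). Defaults g_age = 1, g_bt = 2, g_sf = 1,
  g_crs = 1, σ_g = 2; the intercept g0 = 5.29 was derived analytically from
  the expected covariate values so the cohort mean gradient is ≈ 7.6 mm Hg
  with cohort means near 35 (ETCO2) and 42.5 (PaCO2) mm Hg. Coefficients live
  in `generator_config()` so recovery tests can vary them.

**What the generator does *not* emulate** — and hence what passing tests do
not show about real data: beat-to-beat arterial waveforms (only 1-Hz trends
with idealised surge artifacts), anesthetic events such as bleeding,
repositioning or pneumoperitoneum changes, drifting or recalibrated sensors,
informative missingness (draws here go missing at random), and any real joint
distribution between comorbidity and ventilation strategy. The model-ordering
and attribution-recovery results demonstrate that the *pipeline* recovers
structure it is pointed at, not that the learned model transfers to patients.

## Problem sizes and numerical choices

The packaged study conditions are deliberately desk-scale: the default
end-to-end run uses 300 cases (~900 ABGA events, ~770 modeled), a 20-trial
search, and completes in minutes on one core; the degenerate-limit and
attribution-recovery checks use 100–120 cases. Other conventions: quartiles
use linear interpolation (type 7); a zero-variance detector window defines
all z as 0; a zero IQR in the scaler falls back to scale 1 with a constant
flag; ABGA targets are kept at full precision (no device rounding) so the
degenerate limit (gradient ≡ 5, σ_g = 0) is exactly representable; CSV output
rounds to 6 significant digits; all randomness derives from one global seed
via fixed per-stage offsets recorded in the run manifest.

## Known limitations

The surge detector is validated against the generator's hidden truth, not
against gold-standard draw times — on real data its accuracy is unverified
(and unverifiable without instrumented draws). The ICC confidence interval
assumes the two-way model's normality; with hundreds of events it is
insensitive to that assumption but the p-value should not be over-read.
Subgroup confidence intervals can rest on few folds when a subgroup is rare
(hypocapnia especially); the report warns when folds are skipped. The linear
baseline is fit per outer fold, so its "slope/intercept" is not one number
but seven.
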