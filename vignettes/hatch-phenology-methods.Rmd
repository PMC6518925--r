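---
title: "Modelling hatch phenology of Atlantic salmon embryos"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling hatch phenology of Atlantic salmon embryos}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hatchphen)
```

## The problem

Fall-spawning salmonids incubate their embryos in gravel nests through the
winter, and the seasonal timing of hatch and of spring emergence from the
gravel is a strong determinant of early survival. Because development rate
is governed almost entirely by water temperature, hatch timing is
conventionally tracked on a thermal clock: **accumulated thermal units**
(ATU), the running sum of daily mean water temperatures in °C·days from
fertilization. Development is *not* proportional to ATU — per thermal unit,
embryos develop disproportionately faster below about 5 °C (*compensatory
development*), so cold-incubated embryos hatch at fewer total ATU. Any
usable predictive model therefore has to be non-linear in temperature and
applied incrementally over the actual temperature series an embryo
experiences.

`hatchphen` implements that pipeline end to end: four published
temperature-driven development models for Atlantic salmon (*Salmo salar*),
rate-summation accumulation over arbitrary daily series, logistic
estimation of observed hatch timing from incubation-tube counts,
repeatability statistics for a split-brood experiment, paired evaluation
of observed versus predicted ATU at hatch, and prediction of hatch and
emergence windows in the wild from river temperature records and an
assumed spawning window.

## The development models

Three models express development as a closed-form number of days `D(T)` to
a hatch event at constant temperature `T`; a day at temperature `T` then
contributes the developmental fraction `1/D(T)` and the event fires when
the fractions sum to 1 (rate summation). The fourth (Gorodilov) uses an
absolute developmental clock.

* **Crisp** (daily step, base-10 logs): `log10 D = 5.1908 − 2.6562·log10(T
  + 11.0)`, `D` = days to 50% hatch. The widely cited modern rendering of
  this model prints an undefined intercept term (`log(−11.0)`); we treat
  that as a typographical corruption and use the original Atlantic salmon
  constant 5.1908, exposed as an overridable parameter of `dev_model()`.
* **Gorodilov** (daily step, valid 0.1–11.0 °C): `log10 τs = 3.0984 −
  0.0967·T + 0.00207·T²`, where `τs` is the number of minutes needed to
  form one somite pair at `T`. A day contributes `1440/τs(T)` somite-units;
  50% ("peak") hatch occurs at 315 accumulated units and emergence at 450.
* **WinSIRP** (weekly step, temperature-only form): `D = 11248 /
  (T_wk + 5.3944)^2.0198` with `T_wk` a weekly mean temperature. The full
  software also corrects for dissolved oxygen, pH, flow and waste; those
  terms are deliberately out of scope here.
* **Kane** (daily step, natural log): `ln D = 5.483·e^(−0.0347·T)`, `D` =
  days to **90%** hatch. Kane predicts only the 90% event, so it is
  compared against observed ATU at 90% hatch and has no emergence
  threshold.

### Numerical conventions

* **Clamping.** Daily temperatures below 0.1 °C (Gorodilov's lower validity
  bound) are raised to 0.1 °C for rate evaluation; Gorodilov is also capped
  at 11.0 °C. ATU sums clamp negative daily means to 0 (thermal units are
  non-negative). Both clamps are `dev_model()` / `atu_between()` arguments.
* **Day convention.** The fertilization (or spawn) day is day 0 and
  contributes the first daily increment, so on a constant series the
  accumulated event time equals the closed form exactly (the test suite
  asserts agreement to 1e-6 day for all four models). The crossing day is
  located discretely and linear interpolation within it gives the
  fractional day offset; ATU at the event is pro-rated the same way.
* **Weekly blocks.** `T_wk` is the mean of consecutive non-overlapping
  7-day blocks counted from the start date; every day of a block uses
  `1/D(T_wk)`, and a trailing partial block uses its own mean. A rolling
  mean would be equally defensible; the block scheme is the simplest
  reading of "weekly average temperatures" and is what the tests pin down.
* **Unresolved events.** If a series ends, or development runs into an
  unfilled gap, before a threshold is reached, the event is reported with
  `resolved = FALSE` — never extrapolated.

## Estimating observed hatch timing

Each incubation tube starts with 50 eggs; inspections record newly hatched
and newly dead (removed) eggs per day. `fit_hatch_logistic()` fits a
binomial-logit model of the cumulative proportion hatched against
cumulative ATU at the end of each observation day. Two deliberate choices:

* **Denominator = eggs that eventually hatched.** Hatch *timing* is
  conditional on hatching; mortality is removed continually during the
  protocol and hatch success varies widely between families (34–78% in the
  retained families of the emulated experiment) while timing does not.
  Dead eggs never enter the binomial trials, and the tests assert the
  estimates are invariant to recorded deaths.
* **ATU as the default covariate.** The source analysis does not state
  whether its logistic used ATU or days; both are exposed
  (`covariate = "atu"` / `"days"`), ATU is the default, and DPF₅₀ (days
  post fertilization, fertilization day = 0) is obtained afterwards by
  inverting the cumulative ATU of the series. At constant temperature the
  two parameterizations agree exactly.

Daily cumulative proportions are treated as independent binomial
observations — an approximation (successive days share eggs) that is
adequate for point estimation of the midpoint, which is all the analysis
uses. ATU₅₀ is `−intercept/slope` and ATU₉₀ is `(logit 0.9 −
intercept)/slope`. Degenerate tubes take documented fallback paths: a tube
whose eggs all hatched on one inspection day gets the midpoint between the
last fully-unhatched ATU and the hatch-day ATU (`flag = "single_day"`); a
zero-hatch tube is flagged and excluded. `exclude_low_success()` drops
families whose every tube fell below 15% success, mirroring the exclusion
of one such family (0–14%) in the emulated experiment.

Simulation tests at the design scale (200 tubes of 50 eggs, logistic egg
scale 3 ATU) show mean bias of ATU₅₀ below 1 ATU and RMSE decreasing with
egg count.

## Repeatability statistics

* `icc_oneway()` is the classical one-way random-effects ANOVA estimator
  `(MSB − MSW)/(MSB + (k0 − 1)·MSW)` with `k0` the unbalanced-design
  average group size, and an F-based 95% interval (Searle). The source
  analysis does not state its interval method; the F interval is the
  standard choice for this estimator. The estimator is verified against a
  brute-force ANOVA oracle on every balanced design up to 6×6, and a
  100-replicate simulation at the analysed design size (17 families × 5
  tubes) shows the interval covering the generating ICC in ≥ 90% of seeds.
* `fit_family_model()` fits ATU₅₀ with fertilization date fixed and
  maternal family as a random intercept (REML, via `lme4`/`lmerTest`,
  Satterthwaite denominator df — the same machinery the original analysis
  used). The family intercept is tested with a REML likelihood-ratio test
  on 1 df. The p-value is reported against a plain χ²₁ reference, matching
  how such tests are conventionally printed; because the null puts the
  variance on the boundary of its parameter space this is conservative, so
  the halved p-value is also returned (`lrt_p_boundary`).
* `fit_treatment_model()` adds treatment and its interaction with date as
  fixed effects, pre-averaging the constant-treatment replicates to one
  value per family, since the varying treatments have single tubes.
* `evaluate_models()` pairs observed and predicted ATU at hatch by
  treatment × fertilization date (12 pairs) and reports the mean
  difference **predicted − observed** (negative = the model under-estimates
  the thermal units needed to hatch) with a two-sided paired t-test on 11
  df. Pairs with unresolved accumulations abort the test rather than being
  dropped silently.

## Reconstructing the laboratory regimes

The emulated experiment incubated eggs under one constant regime
(A: ~5.3 °C) and two varying regimes (B: warm spike to 10 °C, C: cool spike
to 2 °C, each for 3–4 weeks in late December–early January, then constant
3.4 °C until hatch). The exact daily profiles are not published; what is
printed per treatment × fertilization date is the mean ± SD temperature
(fertilization until last hatch), ATU₅₀ and DPF₅₀.
`reconstruct_paper_regimes()` rebuilds daily profiles from those summaries:

* Treatment A is constant at the printed per-date mean.
* Treatments B/C use a trapezoid spike: pre-spike baseline `x`, a linear
  ramp of `r` days up to the spike level, a plateau, and a ramp down to the
  printed 3.4 °C post-spike constant, with the varying span starting
  23 December and lasting 21–28 days (the reported 3–4 weeks). Because
  cumulative ATU is affine in `x`, the baseline is solved *exactly* so that
  cumulative ATU at the printed DPF₅₀ equals the printed ATU₅₀ (hard
  feasibility tolerance 2 ATU). The span, ramp length and the last-hatch
  horizon `H ≥ DPF₅₀` are then chosen by grid search so the series mean and
  SD over days 0..H−1 best match the printed values.

Two aspects deserve emphasis. First, the printed mean cannot be matched on
the fertilization→DPF₅₀ horizon — that mean is pinned at ATU₅₀/DPF₅₀ by
definition (e.g. 534/100 = 5.34 °C versus a printed 5.2 °C for the warm
treatment's first date) — which is why the mean/SD constraints are
evaluated over a solved *last-hatch* horizon, exactly how the printed
summary defines itself. Second, the long solved ramps (~8–9 days for the
warm treatment) are what the printed SDs demand: an abrupt plateau with
2-day ramps would give an SD near 2.6 °C against a printed 1.92 °C. The
solved profiles reproduce the printed means within 0.25 °C and SDs within
0.05 °C, with the ATU constraint exact; all residuals are attached to each
series as the `reconstruction` attribute.

This reconstruction is necessarily not unique, and that matters for the
daily-step models: any admissible profile (one hitting the printed ATU₅₀
at DPF₅₀ with the mandatory 3.4 °C tail) bounds the Gorodilov prediction
for the warm treatment well below the observed values, so the paired mean
differences recomputed here for Crisp and Gorodilov are systematically
more negative than the ones reported for the original (unpublished)
profiles. The weekly-averaged WinSIRP model is insensitive to within-week
profile shape, and its recomputed mean difference lands on the reported
−24 ATU almost exactly — evidence that the reconstruction recovers the
coarse structure of the regimes even though the within-week shape is
unidentifiable from the printed summaries.

## The synthetic-data generator

`make_regime()` produces the three regime kinds the pipeline consumes:
constant tanks (optional Gaussian jitter), piecewise spike profiles
(defaults: 10 °C plateau embedded in a 3.4 °C baseline with 2-day ramps),
and river series — a seasonal sinusoid with its minimum (~0 °C) in late
January and summer means of 16–18 °C, plus AR(1) noise (coefficient 0.7,
innovation SD 0.6 °C), clamped at 0 °C. These emulate the structure of
government logger records from temperate salmon rivers: seasonal cycle,
short-term autocorrelation, near-freezing winters.

`simulate_experiment()` generates split-brood experiments with the
variance structure the statistics assume: family shifts `N(0, family_sd)`
(default 8 ATU), tube shifts `N(0, tube_sd)` (4 ATU), per-egg hatch ATU
logistic around the true-model ATU₅₀ with scale 3 ATU, and per-family
hatch success uniform on 0.34–0.78. Defaults mirror the emulated
experiment: 17 families over four November fertilization dates, 50 eggs
per tube, five constant-treatment replicates. The logistic egg
distribution makes the estimation module correctly specified; an
`egg_distribution = "normal"` mode exists for robustness checks. What the
generator does *not* emulate: egg-size/maternal-provisioning effects,
non-stationary mortality, observation gaps, or intra-gravel thermal
buffering — so green tests show the pipeline recovers its own generating
process, not that any particular river behaves this way.

## Wild predictions

`fill_gaps()` linearly interpolates logger gaps of at most 3 days
(configurable) and leaves longer gaps missing so that any accumulation
crossing them is flagged unusable. `predict_windows()` accumulates from
the two boundary spawn dates (or a daily grid) of the spawning window;
the hatch window spans the two 50%-hatch dates and the emergence window
the two 450-unit dates. The default window is 24 October – 7 November: the
source describes the same two-week window with both a "4 October" and a
"24 Oct" start in different places; we read the former as a typo for the
latter (a two-week window starting 4 October would end around 18 October,
not 7 November), and both endpoints are configuration options. A season is
labelled by the year of its spawn start. Predictions use in-stream
temperatures and therefore inherit their known bias relative to
intra-gravel conditions; no correction is attempted.

## Problem sizes and runtime choices

The test suite exercises the estimators at the scales the analysis design
calls for — 200 simulated tubes for logistic recovery, 100 seeded
replicates of the 17 × 5 ICC design, 100 replicate mixed-model fits — and
the acceptance script recomputes the 12-pair model evaluation from the
bundled summary table in about two seconds. All synthetic inputs are
generated in code from fixed seeds; the only stored data are the printed
summary table and the two printed contrast ratios, shipped as small CSVs.
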