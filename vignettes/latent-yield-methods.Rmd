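---
title: "Latent growth-curve phenotypes and ensemble yield prediction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent growth-curve phenotypes and ensemble yield prediction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This package implements a plot-level yield-prediction pipeline for field
breeding trials phenotyped by repeated UAV imagery, in a crop — peanut —
whose yield forms underground and therefore cannot be sensed directly.
The working hypothesis is that the *dynamics* of the visible canopy
(how fast it closes, when growth peaks, how long the rapid phase lasts)
carry more information about pod yield than any single-date snapshot,
and that tree ensembles can learn that mapping. This vignette records
the models, the tunable parameters, the numerical choices, and what the
synthetic data can and cannot establish.

## From imagery to traits

Each plot on each flight date is an RGB tile plus a co-registered
single-band elevation (DEM) tile. Processing is:

1. **Contrast equalization.** CLAHE is applied to the brightness (value)
   channel of the HSV representation only, so hue — the segmentation
   signal — is untouched up to quantization. Defaults: clip limit 2,
   8×8 tile grid. The equalizer requires dimensions divisible by the
   grid; tiles are padded by edge replication and cropped back.
2. **Segmentation.** A pixel is canopy iff its HSV triple lies within
   the bounds (20, 0, 0)–(170, 255, 255), in the half-degree hue
   convention (H ∈ [0, 180), S, V ∈ [0, 255]). The convention is stored
   in the configuration object because the same numbers in a
   full-degree dialect would select a different hue band.
3. **Trait reduction.** Canopy cover (CC) is the canopy-pixel fraction
   of the plot's area of measurement. Canopy height needs a ground
   baseline: the DEM holds absolute elevation, so the median elevation
   of the plot's *soil* pixels is subtracted (5th percentile of the
   whole tile when no soil is visible — e.g. full canopy closure), and
   negative heights are clamped to zero. CH is the mean height over
   canopy pixels and CH90 the 90th percentile (linear interpolation
   between order statistics, R type 7). Canopy volume is defined as
   CV = CC × CH and CV90 = CC × CH90. The excess-green index is
   computed per canopy pixel on chromatic coordinates,
   ExG = 2g − r − b with r = R/(R+G+B) etc.; a two-band g − r variant
   is available behind a configuration switch. Raw ExG means are
   min–max normalized to [0, 1] within each year's batch, so years are
   scaled independently and cross-year comparisons rely on the models,
   not the index scale.

## Growth curves

For each plot, trait and family, the series against days after planting
(DAP, planting day = 0) is fitted with a three-parameter sigmoid:

* logistic: $N(t) = K / (1 + \frac{K - N_0}{N_0} e^{-rt})$, asymptote
  $K$, initial value $N_0$, rate $r$ (day⁻¹);
* Gompertz: $N(t) = N_0 \exp(-\beta e^{-\alpha t})$, where $N_0$ is the
  *upper asymptote*, $\beta$ the displacement and $\alpha$ the rate
  (day⁻¹). (The parameter name $N_0$ is kept for continuity with the
  field's notation even though the curve's value at $t = 0$ is
  $N_0 e^{-\beta}$.)

Missing plot×date cells (rare, completely at random in the generator)
are first filled with the same-date, same-year trait mean so every plot
has a complete series; filled cells are flagged.

Fitting is bounded Levenberg–Marquardt least squares. Initialization is
deterministic: the asymptote starts at 1.05 × the observed maximum, and
the rate and displacement come from regressing the appropriate
linearization (logit for logistic, log(−log) for Gompertz) on DAP;
three fixed rescalings of that start serve as restarts, attempted only
when the incumbent fit is poor, so clean fits cost one optimizer run.
Bounds keep the optimizer in the biologically plausible basin:
asymptote ≤ 2 × max observed (≤ 1 additionally for CC, since cover is a
fraction), rates in [10⁻⁴, 1] day⁻¹, β in [10⁻³, 10³]. A fit that fails
every start is returned with `converged = FALSE` and excluded from the
feature pool. Late-season declines (ExG senescence) are fitted as-is —
the sigmoid is the stated model — and the per-fit R² is carried so
users can filter.

## The 14 latent phenotypes

From each fitted curve $N(t)$ and its analytic derivative $N'(t)$,
within the observed window $[t_a, t_b]$:

| code | definition |
|------|------------|
| f1 | $N(t^*)$, value at the inflection $t^*$ |
| f2, f3 | DAP where $N(t)$ reaches 50% / 80% of f1 |
| f4 | DAP at inflection ($t^* = \ln\beta/\alpha$ or $\ln A/r$) |
| f5 | $N(t_b)$, the window-limited maximum |
| f6, f7 | DAP and value of the growth-rate peak (f6 = f4 for sigmoids) |
| f8, f9 | DAP of first/last half-maximum growth rate |
| f10 | f9 − f8 |
| f11 | $\int_{t_a}^{t_b} N'(t)\,dt = N(t_b) - N(t_a)$ |
| f12 | f11 / (t_b − t_a) |
| f13, f14 | $\pm f_7 / (2(f_6 - f_8))$, $-f_7/(2(f_9 - f_6))$: rate-curve rise/fall slopes |

Design choices where the definitions were genuinely open: f2/f3 are
read as fractions of the inflection *value* (the only reading that
makes them distinct and computable from the curve alone); f5 is the
end-of-window value rather than the asymptote, because the asymptote
may be unreachable within the season (switchable); f13/f14 are the
slopes between the half-maximum crossings and the peak of the rate
curve, signed so increase is positive and decrease negative. Crossings
are found by root bisection on the analytic curves to 10⁻⁸ days — one
code path for both families — while the Lambert-W and logistic closed
forms serve as independent test oracles. A crossing outside the
observed window is clipped to the window bound and flagged. Inflection
and peak-rate values use closed forms.

The pool is one row per plot, one column per trait × family × feature
(`CC_gompertz_f9`), 168 candidates for 6 traits × 2 families.

## Feature selection

**VIF.** Each feature is regressed on all others; VIF = 1/(1 − R²).
Removal is iterative — drop the single worst feature above 5, recompute —
because a one-shot pass over-removes mutually collinear groups. With
168 closed-form features of 3-parameter curves the pool is almost
perfectly collinear, and the gate is intentionally harsh: typically
only ~13 survive. Survivors that remain merely *strongly* correlated
are kept. Constant columns (undefined VIF) are dropped first with a
warning; an auxiliary R² that rounds to 1 is recorded as infinite.

**RFE.** Per Monte-Carlo split, one backward-elimination path is
computed on the training set (fit, drop the least important feature by
the learner's own ranking — impurity for the forest, gain for boosting —
refit), and every limit 1–30 is read off that path and rescored. The
chosen limit is the smallest whose mean test adjusted R² is within
0.005 of the sweep peak.

## Yield models and validation

Defaults are the grid-search optima used throughout: random forest with
400 trees of depth 10 (all features considered per split, mirroring the
regression default of the reference implementation of this protocol),
and gradient boosting with learning rate 0.06, depth 3, minimum child
weight 5, 100 rounds. A seeded, exhaustive grid search over
depth {5, 10, 15, unlimited} × trees {100, 200, 400, 800} (forest) and
lr {0.03, 0.06, 0.1} × depth {3, 5, 7} × min child weight {1, 3, 5}
(boosting) is provided, scored by 5-fold CV with ties to the simpler
model.

Validation is Monte-Carlo cross-validation: each random state draws a
fresh 70/30 train/test split (or a split fraction from
{0.5, …, 0.9} in variable mode), fits, and scores both sets with
adjusted R² = 1 − (1 − R²)(n − 1)/(n − p − 1), each set using its own
n. States whose test set has n ≤ p + 1 are skipped and logged. The
best state — highest test adjusted R², ties broken by training score —
is retained and predicts yield for *every* plot, labelled by that
state's train/test membership. 10-fold CV is run alongside as a
protocol check. All randomness derives from one integer seed
(sub-seeds are generated by fixed integer arithmetic, kept below 2³¹),
and the caller's RNG state is never disturbed.

## Evaluation for breeding

* Per-flight Pearson correlations between each trait on each date and
  final yield, per year.
* OLS of estimated on measured yield, overall and per year — per-year
  fits guard against the inflation produced when two years with very
  different yield levels anchor a single pooled regression.
* Repeatability by method-of-moments on the one-way random-genotype
  ANOVA: σ²ₑ = MS within, σ²𝘨 = (MS between − MS within)/r̄ with r̄ the
  mean replicate count, truncated at zero and flagged when negative;
  R = σ²𝘨/(σ²𝘨 + σ²ₑ/r̄) on an entry-mean basis. Method-of-moments is
  deterministic and matches the all-random one-way model; a REML fit of
  the same model is a drop-in alternative the user can run with lme4.
* Genotype means are ranked into Excellent (top 10%), Good (11–25%),
  Mediocre (26–50%) and Poor (bottom half); cumulative boundaries are
  rounded half up so the partition is exact for any count, ties broken
  by stable genotype order. Each prediction method bins by its *own*
  percentile ranks, making the confusion matrix a pure
  ranking-agreement measure; the Excellent↔Poor cells are reported
  separately as catastrophic selection errors.

## The synthetic generator, and what passing means

No field data ship with the package; the generator defines the study
conditions: 73 genotypes × 3 replicates per year, 12 flight dates in
the first year and 18 in the second spanning 10–130 DAP, 1% of
plot×date cells missing at random. Genotype-level Gompertz parameters
are drawn log-normally (CV 10%) around trait medians (CC: asymptote
0.90, β 8, α 0.08 day⁻¹; CH: 0.45 m; CH90: 0.55 m; ExG: 0.80; all with
comparable rates), plot-level parameters jitter those by a 5% CV, and
observations add Gaussian noise (SD 0.02 in trait units). Yield
(t/ha) is a linear function of five latent features of the plot's
*true* canopy-cover curve — positive on canopy size and peak growth
rate, negative on late phenology — plus a genotype effect (SD 0.35), a
year offset (±0.4) and a Gaussian residual (SD 0.30); the coefficients
were set so the five features contribute comparable variance and the
latent signal dominates, emulating trials in which growth dynamics
drive yield. A `target_r2` mode instead sets the residual SD from the
realized signal variance, giving parameter-recovery tests a known
answer. Rendered tiles use one soil hue and one canopy hue with exact
pixel counts — enough to exercise the segmentation arithmetic, not a
radiometric simulation.

What the passing suite shows: the closed-form identities of both curve
families; exact recovery of noiseless trajectories and median α error
under 10% at realistic noise; exact recovery of rendered tile geometry;
and that a trial whose true feature-signal R² is 0.85 comes back from
the *full* pipeline (simulate → fit → extract → MCCV forest) with a
mean test adjusted R² within ±0.1 of that truth. What it cannot show:
robustness to real-world segmentation failures (weeds, shadows, mixed
pixels), non-sigmoid stress trajectories, spatial field trend, or
genotype-by-environment structure — none of which the generator
emulates.

## Problem sizes and costs

The default analysis (both years, 438 plots, 6 traits × 2 families =
5 256 curve fits, 168-feature pool, RFE sweeps with 5 re-splits, two
learners at 200 MCCV states) completes in a few minutes on one core;
the test suite runs in well under a minute apart from the two
simulation studies (200 noisy refits; 200-state end-to-end recovery),
which together take about a minute. The MCCV state count is a
parameter: 200 states estimate the mean adjusted R² to ±0.005 or so on
these data, and the full 1 000-state protocol is one argument away.

## Known limitations

* The Gompertz-vs-logistic comparison is by downstream predictive
  utility only; no information criterion is reported per fit beyond R².
* Iterative VIF at threshold 5 is order-dependent where VIFs tie; ties
  are broken deterministically (first-worst wins) for reproducibility.
* CV = CC × CH is a biomass-envelope proxy, not a volume integral over
  the height distribution.
* Adjusted R² can be strongly negative on small test sets; the MCCV
  skip rule (n_test ≤ p + 1) protects the denominator but small-sample
  scores remain noisy.
* The two-cluster inflation guard is a reporting convention (per-year
  regressions), not a statistical correction.
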