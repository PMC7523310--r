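---
title: "Modelling longitudinal mammographic density change: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling longitudinal mammographic density change: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdchange)
```

# The scientific problem

Mammographic density — the proportion or absolute amount of radiodense
fibroglandular tissue on a mammogram — is both a breast-cancer risk factor
and a candidate response biomarker for tamoxifen preventive therapy: women
whose density falls under tamoxifen may be the ones who benefit. Automated
density algorithms (area-based readers and volumetric readers) produce one
number per image; before density *change* can guide individual decisions,
three questions must be answered:

1. **Size**: how much does density fall in the first year of therapy, and
   does it keep falling?
2. **Reliability**: how much of the variation in a single reading is real
   between-woman signal rather than measurement error?
3. **Stability**: is a woman's *own* observed 1-year change informative
   about her subsequent change, or is it dominated by noise?

`mdchange` implements an analysis pipeline for these questions on
longitudinal two-group (treated / untreated) cohorts with annual mammograms,
together with a synthetic-cohort generator so that every stage is testable
without patient data.

# Cohort construction

The ingestion format is one long CSV row per (woman, visit, measure). The
pipeline applies, in order:

* **View aggregation** (`aggregate_views()`): the per-visit value of a
  measure is the arithmetic mean over the available views of both breasts
  (up to four images). Missing individual images are averaged over rather
  than discarding the visit, since per-view failures are sporadic.
* **Completeness filtering** (`filter_complete_timepoints()`): a visit is
  analysed only if *every* analysed measure produced a value there, so that
  all measures are compared on identical mammograms. Incomplete visits are
  dropped wholesale.
* **On-treatment censoring** (`censor_on_treatment()`): for treated women,
  visits after drug cessation are removed; the baseline (pre-treatment)
  visit is always kept. Visit times are integer years (annual clinics).
  Censoring is strict at the recorded stop time — a visit nominally "at one
  year" occurring after cessation within that year is excluded.
* **Matching** (`match_controls()`): each treated woman receives up to two
  untreated controls with baseline age within one year and the same baseline
  calendar year. When more controls are eligible than needed, the smallest
  absolute age difference wins, with lexicographic id as the tie-break —
  a deterministic rule chosen for reproducibility.
* **Nested analysis samples** (`build_samples()`): sample A (baseline
  density available), B (additionally year 1), C (additionally year 2), with
  C ⊆ B ⊆ A by construction. Descriptives and model fits use A; cutpoint
  classification and the stability test need both follow-up changes and use
  C.

Age and BMI are frozen at baseline: weight is typically not monitored
through follow-up in such cohorts, so a time-varying adjustment is not
identifiable. Missing BMI is imputed by the mean of the observed values,
pooled over both groups (`impute_bmi()`); with treatment assignment
unrelated to BMI measurement this is innocuous for the time-by-group
contrasts that carry the scientific conclusions.

# Transformation and standardisation

Density distributions are right-skewed. Area-based percentage measures are
square-root transformed; volumetric percentage density and dense volume are
natural-log transformed (a change in log volumetric density is a relative
change). Zero percent is admissible under the square root; non-positive
values under the log are an error rather than silently offset, since
volumetric readers do not produce zeros in practice.

To compare effect sizes across algorithms with different native scales, each
transformed measure is standardised to **zero mean and unit inter-quartile
range at baseline** (`fit_standardization()`, `standardize()`). One unit on
the analysis scale is therefore one baseline IQR of that measure. Quartiles
use linear interpolation between order statistics (R's default type 7); the
convention is fixed and documented because the IQR enters every reported
effect size. Display conventions (changes ×10 in the cutpoint table, MSE
×100 in the stability table) are applied only at output formatting.

Between-measure agreement is summarised by a weighted Pearson correlation
over all paired visits (`repeated_measures_correlation()`), with each
observation of woman *i* weighted 1/n~i~ so every woman contributes equal
total weight regardless of her follow-up length. This targets the
between-women association; an unweighted correlation would let
long-follow-up women dominate. Percentage density is expected to correlate
*negatively* with breast size measures, which sit in its denominator — the
package's property tests check this sign.

# The step-and-ramp mixed model

For each measure, the standardised density y~ij~ of woman *i* at visit time
t~ij~ (years) follows a normal linear mixed model fitted by maximum
likelihood (`fit_density_lmm()`, on `lme4::lmer`, `REML = FALSE`):

$$
y_{ij} = \beta_1 + \beta_2 g_i + \beta_3 \frac{\text{age}_i}{5}
       + \beta_4 \frac{\text{BMI}_i}{5}
       + \beta_5 \, 1\{t_{ij} \ge 1\} + \beta_6 (t_{ij}-1)_+
       + \beta_7 g_i 1\{t_{ij} \ge 1\} + \beta_8 g_i (t_{ij}-1)_+
       + a_i + b_i t_{ij} + \varepsilon_{ij}
$$

with g~i~ the treatment indicator, (a~i~, b~i~) bivariate-normal random
intercept and slope, and independent residuals. The time coding is the
unique piecewise form in which β~5~ + β~7~ give a *different change at one
year* between the groups (the acute "step") and β~6~ + β~8~ give *different
yearly rates from year 2 onwards* (the sustained "ramp"): the indicator
1{t ≥ 1} carries the jump, and the hinge (t−1)~+~ is zero through year 1 so
the two effects do not alias. Because y is in baseline-IQR units, −100·β~7~
reads directly as "year-1 decline as a percentage of the baseline IQR".

Profile-likelihood confidence intervals (`profile_ci()`) are used for the
fixed effects: bounds sit where twice the profile log-likelihood drop equals
the χ²(1) quantile. If profiling fails to bracket, a Wald interval is
returned and flagged. Wald-style intervals are used for variance
components.

## Reliability (ICC)

Reliability is the between-woman share of variance,
$\mathrm{ICC}(t) = \mathrm{var}_B(t) / (\mathrm{var}_B(t) + \sigma^2_\varepsilon)$
with $\mathrm{var}_B(t) = \sigma^2_a + 2t\,\sigma_{ab} + t^2 \sigma^2_b$;
one minus the ICC is the measurement-error share. With a random slope the
between-woman variance is time-dependent, and `icc_from_fit()` evaluates at
baseline (t = 0) by default, with a `time` argument for other choices. The
complementary ratio (residual over total) is exposed as
`measurement_error_share()`: a high ICC means a reliable measure, and the
two numbers always sum to one.

The ICC interval is a non-parametric cluster bootstrap
(`bootstrap_icc()`, default 3000 resamples): *women* are resampled with
replacement, each keeping her whole trajectory, the model is refitted, and
percentile bounds are taken. Resampling the woman — not the visit — is the
only resampling unit consistent with the within-woman dependence.

In a sensitivity refit on the treated group alone (`fit_tamoxifen_only()`,
dropping the group terms), the estimated intercept–slope correlation is of
direct interest: a negative value means women with higher baseline density
experience larger declines.

# Control-calibrated cutpoints

To classify individual change against an external benchmark (a visual
10-percentage-point decrease rule), each automated measure's "decrease"
threshold is calibrated on the *control* group: the cutpoint is the k-th
smallest control change, where k is the number of control women the
benchmark classifies as decreased (`calibrate_cutpoint()`). By construction
exactly k controls fall at or below the cutpoint — the package treats this
count-matching as exact and errors on ties rather than silently returning
the nearest achievable count (ties cannot occur with continuous changes but
can with rounded file input). Classification (`classify_change()`) is
three-way with inclusive boundaries: change ≥ 0 is "no change", change at or
below the cutpoint is "decrease", anything between is "intermediate".
Cutpoints calibrated on 1-year changes are reused unchanged at 2 years, so
the two horizons are compared against the same yardstick.

The group contrast is the decrease difference — treated minus control
percentage classified as "decrease" — with a Newcombe hybrid-score interval
by default (`decrease_difference()`; a Wald interval is available via
`method`). The point estimate is exact arithmetic on the counts; the CI
method is a presentation choice.

# The prequential stability test

A change measure is *stable* if a woman's own observed 1-year change
(δ~1~ = y(1) − y(0)) predicts her 2-year change (δ~2~ = y(2) − y(0)) better
than the cohort mean 1-year change does, under squared-error loss
(`prequential_mse()`), in the treated women of sample C. Both horizons are
anchored at baseline, matching the convention of the classification table.
The relative MSE (individual / reference) exceeding 1 means the measure is
unstable: telling every woman "your density changed by the average amount"
out-predicts telling her what her own mammogram showed. The percentile
bootstrap for the ratio (`bootstrap_relative()`) resamples women and
*recomputes the cohort-mean predictor inside every resample*, so its
sampling uncertainty is propagated; 3000 resamples by default, mirroring the
ICC bootstrap.

## Closed-form behaviour and what the generator can and cannot emulate

Write δ~1~ = d + e~1~ and δ~2~ = d + e~2~ with a common signal d and
independent errors of variance σ² at each horizon, and between-woman signal
variance τ². Then as n → ∞ the relative MSE tends to
$2\sigma^2 / (\tau^2 + \sigma^2)$: 2 under pure noise (τ² = 0), below 1 once
τ² > σ². The package's tests track this curve across τ²/σ² ∈
{0, 0.5, 1, 2, 4}.

One algebraic subtlety deserves emphasis. When both change scores share the
*same measured baseline*, the baseline error e~0~ appears in both δ~1~ and
δ~2~ and cancels out of their difference, which *couples* the two scores:
with iid error at every visit (including baseline) and no slope
heterogeneity the relative MSE tends to 1, not 2, and with slope
heterogeneity it falls below 1. The idealised noise-dominant limit of 2
therefore presumes the baseline is effectively error-free relative to the
follow-up readings. Accordingly the `noise_dominant` scenario of
`scenario_library()` pins the baseline (zero baseline residual), sets slope
variance and treatment effects to zero, and disables attrition and
missingness; under it the full pipeline converges to 2 as the closed form
says. The default `paper_like` scenario keeps baseline noise and therefore
does **not** produce large instability ratios: reproducing empirically
observed relative MSEs well above 1 would require horizon-specific
fluctuation (e.g. biological density variation concentrated at particular
visits) whose structure is not identifiable from published summary
statistics, and the generator deliberately does not invent it. What passing
the stability tests shows is that the estimator and its bootstrap behave
correctly in regimes with known answers — not that synthetic cohorts mimic
every feature of real instability.

A second indicator of instability is classification disagreement
(`threshold_agreement()`): the fraction of women whose three-way category
differs between the 1-year and 2-year horizons under the same cutpoint.

# The synthetic-cohort generator

`generate_cohort()` draws cohorts with the statistical structure the
analysis assumes; `generator_config()` holds the study conditions, and the
defaults are fixed once:

* **Design**: 126 treated women; each receives one matched control always
  and a second with probability 0.37 (≈1.37 controls per case, ≈172
  controls); control age is the case age ± 1 year, same baseline calendar
  year (2010–2013). Case age is normal (median 42, SD 5, truncated 30–55).
  BMI is log-normal (median ≈ 25.5 kg/m²) with 10% missing.
* **Baseline density**: per measure, the between-woman baseline follows a
  scaled-beta marginal on the native percent scale (log-normal for
  volumetric measures), moment-matched on the transformed scale to target
  medians and quartiles typical of premenopausal high-risk populations
  (e.g. volumetric percent median 8.6, quartiles 5.4–15.7; area percent
  medians ≈ 38–41). Measures are coupled by a one-factor Gaussian copula
  with cross-measure correlation 0.9.
* **Trajectories**: on the standardised scale, the mean follows the
  step-and-ramp fixed effects (defaults: treated step −0.21 and ramp
  −0.045 IQR units; all other effects 0), plus a woman-level random slope
  (SD 0.08 IQR/year) correlated −0.45 with her baseline level, plus
  residual noise. Variance components default to
  var~intercept~ = 0.9/1.349², var~resid~ = 0.1/1.349², which makes the
  observed (noise-inclusive) baseline have unit IQR in target-IQR units and
  a baseline ICC of exactly 0.9. Within-visit residuals share a
  cross-measure correlation of 0.3, which lifts the repeated-measures
  correlation of the generated percentage measures above 0.8.
* **Follow-up**: administrative follow-up is uniform on 1–5 years (median
  3); treated women stop therapy according to a stop-time distribution with
  roughly 1% never starting, 21% stopping within year 1, then 8%, 12%, 5%,
  2% in successive years and 52% completing, uniform within each interval;
  post-cessation visits are never generated. Follow-up readings are
  missing per measure with probability 0.05; baselines are complete, so
  sample A is the full cohort.
* **Clipping**: inverse-transforming a trajectory can leave the
  representable percent range; values are clipped into [0, 100] and every
  clip is counted in `clip_events`. Clipping mainly affects
  square-root-transformed measures with wide baseline spread near 0%, and
  is the reason estimator-recovery checks use the volumetric (log) measure,
  whose generator marginal is exactly Gaussian on the analysis scale and
  whose fitted model is therefore exactly correctly specified.

Generation is a pure function of the config, including its seed.
`scenario_library()` provides `paper_like`, `noise_dominant`,
`signal_dominant` (slope variance ≫ residual variance, so individual change
is genuinely predictive) and `null` (no treatment effects, for type-I-error
checks).

# Numerical choices

* The mixed model is fitted by ML via `lme4`; if the default optimizer
  raises a gradient-tolerance warning (often spurious at moderate sizes),
  the fit is retried with `bobyqa` before being flagged non-converged.
  Singular fits (e.g. zero slope variance under `noise_dominant`) are
  flagged but usable; downstream operations refuse genuinely non-converged
  fits.
* Bootstrap refits skip derivative-based convergence checks for speed;
  refit failures are counted and more than 5% is an error, not a silent
  degradation.
* All bootstraps and the generator take explicit integer seeds; identical
  seeds reproduce every table byte-for-byte, and RNG state is restored on
  exit so library calls do not perturb the caller's stream.
* Degenerate inputs fail loudly: zero baseline IQR, all-missing BMI,
  all-missing images at a visit, log of non-positive density, cutpoint ties,
  zero reference MSE.

# Problem sizes used in the test suite

The packaged checks run at sizes chosen to give tight Monte-Carlo error
while remaining desk-scale: parameter recovery uses 200 replicate cohorts of
300 cases (≈710 women each), which bounds the Monte-Carlo SE of the mean
year-1 step estimate at ≈0.002 IQR units; the noise-dominant stability limit
uses one cohort of 2000 treated completers; reproducibility checks run the
full pipeline with 200 bootstrap resamples. The analysis scripts use a
126-case cohort matching the motivating study design, with 500–1000
bootstrap resamples; a full analysis would use the package default of 3000.

# Known limitations

* The generator emulates summary structure (marginals, correlations,
  variance components, attrition), not mammograms or reader behaviour;
  algorithm-specific artefacts, machine effects and within-year biological
  fluctuation are out of scope, and the instability of real 1-year change
  is correspondingly under-represented under `paper_like` (see above).
* Only the two predictors named in the stability definition are compared;
  shrinkage predictors interpolating between them would be a natural
  extension but are deliberately not implemented.
* Alternative variance-stabilising transforms (e.g. Box–Cox) would change
  point estimates on the standardised scale; only sqrt/log are provided.
* Profile intervals are provided for fixed effects; variance components get
  Wald-style summaries only.
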