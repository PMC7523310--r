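# mdchange

Longitudinal change, reliability and stability of mammographic density
measures in tamoxifen-prevention cohorts.

Mammographic density falls under tamoxifen, and the size of a woman's
density decline is a candidate biomarker of drug benefit. Before 1-year
density change can guide individual decisions (e.g. stopping therapy when no
change is seen), three properties of the automated density measures must be
quantified on longitudinal two-group data:

* **Size of change** — a normal linear mixed model with a *step-and-ramp*
  time effect: for woman *i* at time *t* (years), standardised density

  ```
  y_it = b1 + b2 g_i + b3 age_i/5 + b4 bmi_i/5
       + b5 1{t>=1} + b6 (t-1)+ + b7 g_i 1{t>=1} + b8 g_i (t-1)+
       + a_i + s_i t + e_it
  ```

  with treatment indicator `g`, bivariate-normal random intercept/slope
  `(a_i, s_i)`, ML fit, and profile-likelihood CIs. Densities are sqrt- or
  log-transformed and standardised to unit baseline inter-quartile range,
  so `-100*b7` is the year-1 treated-group decline as a percentage of the
  baseline IQR and `-100*b8` the yearly decline thereafter.
* **Reliability** — the intraclass correlation (between-woman share of
  variance) from the model, with a cluster-bootstrap percentile CI.
* **Stability** — a prequential test: is a woman's own observed 1-year
  change a better predictor of her 2-year change than the cohort mean
  1-year change, under squared-error loss? A relative MSE above 1 means the
  measure is unstable at the individual level.

The package also provides control-calibrated cutpoints for classifying
"density decrease" against an external benchmark, nested analysis-sample
construction with on-treatment censoring and age/calendar matching, and a
synthetic-cohort generator (`generate_cohort()`, `scenario_library()`) that
reproduces the statistical structure of such studies so the entire pipeline
is testable without patient data.

## Worked example

The numbered scripts under `analysis/` run the full workflow on a synthetic
126-case cohort and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R      # generate the cohort (long CSV)
Rscript analysis/02_descriptives.R  # baseline/year-1 summaries, correlations
Rscript analysis/03_mixed_models.R  # step-and-ramp fits, ICC, sensitivity refit
Rscript analysis/04_cutpoints.R     # calibrated cutpoints, 3-way classification
Rscript analysis/05_stability.R     # prequential stability test
```

`analysis/03_mixed_models.R` prints, for this cohort (step/ramp in baseline
IQR units with 95% profile CIs):

```
stratus_pct   step -0.320 (-0.406, -0.235)  ramp -0.017 (-0.063, 0.028)  ICC 0.86 (0.83-0.88)  corr -0.65
densitas_pct  step -0.185 (-0.267, -0.104)  ramp -0.026 (-0.070, 0.018)  ICC 0.89 (0.86-0.90)  corr -0.38
nnvas_pct     step -0.316 (-0.411, -0.221)  ramp -0.043 (-0.090, 0.003)  ICC 0.88 (0.85-0.90)  corr -0.39
volpara_pct   step -0.308 (-0.392, -0.224)  ramp -0.010 (-0.053, 0.034)  ICC 0.89 (0.86-0.91)  corr -0.54

Year-1 decline across measures: 19-32% of baseline IQR;
yearly decline thereafter: 1.0-4.3% of IQR per year.
```

i.e. every measure shows a large acute decline at one year in the treated
group, a continued smaller decline thereafter, high reliability
(ICC ≈ 0.9), and a negative intercept–slope correlation (larger declines in
women with higher baseline density). `analysis/05_stability.R` then shows
that in the idealised noise-dominant regime the relative MSE of individual
1-year change reaches its closed-form limit:

```
noise-dominant scenario (n = 2000): relative MSE 2.03 (closed-form limit 2)
```

Equivalent one-call interface:

```r
library(mdchange)
bundle <- run_pipeline(generator_config(n_cases = 126, seed = 17),
                       boot = 500, seed = 17)
bundle$model_table   # effects, profile CIs, variance components, ICC
bundle$table3        # calibrated cutpoints and decrease differences
bundle$table4        # prequential stability (MSE x100, relative, CI)
```

The package also ships, under `inst/extdata/`, the published classification
counts and MSE table of the motivating study, from which the printed
decrease differences (21, 47, 46, 47, 37, 40, 44, 39, 51 percentage points)
and relative predictive performances (2.4, 3.1, 2.4, 1.6) are recomputed
exactly (`reference_decrease_differences()`, `reference_relative_mse()`).

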