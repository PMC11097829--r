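---
title: "Stratified non-linear Mendelian randomisation: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stratified non-linear Mendelian randomisation: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stratamr)
```

## The estimand and the two stratification methods

Let `g` be a weighted genetic score instrumenting a continuous exposure
`x` (BMI, kg/m²), and let the outcome be time to death on the age
timescale. Non-linear Mendelian randomisation asks how the causal effect
of `x` on the log-hazard varies with the level of `x`. The population is
divided into `Q` ordered strata of the exposure distribution, a localised
average causal effect (LACE) is estimated in each stratum as the ratio of
the instrument-outcome to the instrument-exposure association, and the
LACE series is smoothed into a curve.

The difficulty is constructing strata within which `g` remains a valid
instrument. Stratifying on `x` directly conditions on a collider
(`x` is caused by both `g` and the confounders), so `stratamr` implements
the two principled alternatives:

* **Residual method**: strata are quantile groups of
  `x − E[x | g]`. The residual is independent of `g` by construction, but
  instrument validity inside the strata additionally requires the
  *constant genetic effect* assumption — `g` shifts every individual's
  exposure by the same amount. `stratify(method = "residual")`
  residualises on the score alone by default, matching the method's
  definition; covariate-adjusted residualisation is available through the
  `covariates` argument.
* **Doubly-ranked method**: sort by `g`, cut consecutive *prestrata of
  size Q* (so there are `n/Q` prestrata), and within each prestratum send
  the k-th smallest exposure to stratum `k`. Every prestratum contributes
  exactly one member to every stratum, so the instrument distribution is
  (nearly) identical across strata by construction. Validity requires
  only the *rank-preserving* assumption: the ordering of individuals by
  exposure would be unchanged at any fixed instrument value.

Two implementation details are not fixed by the method's published
construction and are this package's choices, recorded in the assignment
object and its JSON export: score ties are broken by a seeded random
perturbation applied to ranks only (stored values are never modified),
and when `n mod Q ≠ 0` the remainder individuals are removed by a seeded
random draw and listed in `trimmed_ids`. Both choices make reruns exactly
reproducible.

## Stratum estimation

Within each stratum, `beta_gx` is the least-squares slope of exposure on
the score standardised to unit SD over the analytic sample, and `beta_gy`
the log hazard ratio per SD of score from Cox proportional-hazards
regression with attained age as the timescale — `Surv(entry_age,
exit_age, event)`, i.e. delayed entry at recruitment age — with Efron tie
handling. Efron's approximation is preferred to Breslow's because event
ages are heavily tied in large cohorts, and it is deterministic. Both
regressions take the same additive covariates; the conventional set
`age + age² + sex` is partially redundant with the age timescale but
retained because it is what large-cohort analyses adjust for, and
baseline age (a cohort effect) is not controlled by the timescale itself.

The LACE is `beta_gy / beta_gx` with first-order delta standard error
`se(beta_gy)/|beta_gx|`. The first-order form ignores the sampling error
of the denominator; with individual-level data and per-stratum F
statistics around 20 this is the conventional choice, and a second-order
option (`second_order = TRUE`) adds the denominator term. Strata with
`|beta_gx|` below a configurable floor (default `1e-6`), zero score
variance, no events, or a monotone partial likelihood are excluded and
listed with reasons rather than silently dropped.

`covariate_check()` regresses candidate competing risk factors on the
standardised score, overall and per stratum, by linear regression even
for binary traits so that associations are comparable across strata on
one scale (odds ratios would confound the visual diagnostic with
baseline-rate differences). Trait-on-score rather than score-on-trait is
used so every trait is reported per SD of the same score.

## Fractional-polynomial meta-regression

The LACE in stratum `s` estimates the derivative `h'(x)` of the causal
curve at the stratum's mean exposure. The package fits
`h(x) = Σ_j β_j x^{p_j}` with powers from the canonical set
{−2, −1, −0.5, 0, 0.5, 1, 2, 3} (`x^0 ≡ ln x`; a repeated power at
degree 2 contributes `x^p ln x`, or `(ln x)²` at `p = 0`), by regressing
the LACE estimates on the *analytic derivative* of this basis at the
stratum means — weighted least squares, weights `1/SE²`, no intercept.
Powers are selected by maximising the weighted Gaussian log-likelihood
over all 8 degree-1 powers and 36 degree-2 multisets; singular candidate
designs are skipped and logged. The error model is fixed-effect (known
variances); Cochran's Q over the selected fit is reported as a
heterogeneity diagnostic only.

The curve is reconstructed as `h(x) − h(x_ref)` with pointwise variance
from the coefficient covariance, so it is identically 0 with zero
variance at the reference (default 25 kg/m², the conventional
normal-weight boundary; the reference is arbitrary and only shifts the
curve vertically). The default grid is 200 equally spaced points between
the 1st and 99th percentiles of the stratum means, with the reference
forced onto the grid. Effect statements are read off the confidence
bounds, not the point estimate: a harmful effect is *evident* above the
smallest grid value beyond which both bounds have positive
finite-difference slope (`effect_evident()`), and these thresholds are
always recomputed from the curve, never stored.

Both degrees are always fitted. The reported curve defaults to degree 2,
because degree-1 polynomials are dominated by the upper end of the
exposure distribution — where instruments are strongest and most events
occur — and smooth over imprecise estimates at the lower end, hiding
genuine uncertainty about the curve's shape there.

Two tests summarise non-linearity. The **linearity test** refers twice
the log-likelihood gap between the best degree-1 polynomial and the
linear model (power 1) to χ²(1); because the best power is selected by
maximum likelihood without a multiplicity adjustment, the reference
distribution is approximate and the test mildly anti-conservative — at
the package's test scale (500 replicates, n = 20 000, Q = 20, linear
truth) the measured size is about 0.02–0.06 at nominal 0.05. The **trend
test** is the known-variance normal test of the slope in the weighted
meta-regression of LACE on stratum mean exposure; its z-statistic was
measured at sd ≈ 1.05 under the null at the same scale, a small
anti-conservatism inherited from treating estimated ratio SEs as known.

## Sample perturbation and Rubin's rules

Doubly-ranked assignments can change visibly when a handful of
individuals enter or leave the sample, because removals shift the
prestratum boundaries. `perturb_iterate()` repeats the stratification and
LACE estimation `m` times (default 100), each time removing `n_remove`
individuals (default 12) uniformly without replacement; the removal seed
for iteration `i` is `seed XOR i`, while the stratification configuration
— including its tie-break seed — is held fixed, so with `n_remove = 0`
every iteration reproduces the unperturbed analysis exactly.
`pool_lace()` combines per stratum by Rubin's rules: point = mean of
points, total variance = mean squared SE + (1 + 1/m) × between-iteration
variance. Combination happens at the stratum-LACE level and the
meta-regression is then run once on the combined set — the LACE is the
quantity whose sampling instability motivates the procedure; a
per-iteration-curve alternative would pool across differing selected
powers. Combined intervals use the normal approximation (`m = 100` is
large); iterations missing a stratum are dropped pairwise for that
stratum, and per-iteration test p-values can be inspected from the
iteration list rather than pooled into a single combined p-value, whose
distribution under Rubin combination is not well defined.

## The synthetic cohort generator

`simulate_cohort()` emulates the structure that stratified MR of
adiposity on mortality assumes, with defaults chosen to resemble large
adult European-ancestry cohorts:

* **Genotypes and score**: independent biallelic variants (default 25,
  frequencies spread over \[0.1, 0.9\]), dosage-weighted score. The
  score's share of exposure variance is calibrated in-sample to
  `target_r2` (default 0.02, the order explained by a 73-variant adult
  BMI score; F-statistics at these settings are in the thousands for the
  full sample).
* **Heterogeneity**: the per-individual instrument effect is
  `base × (1 + heterogeneity · Φ(L))`, where `L` is the standardised
  non-genetic exposure component. The multiplier is positive and monotone
  in exposure liability, so the rank-preserving assumption holds by
  construction while the constant-effect assumption is violated whenever
  `heterogeneity > 0` — the dial is the study condition the doubly-ranked
  method exists for. Settings of 2 and 6 give top/bottom percentile slope
  ratios of roughly 3 and 7, the orders reported for Norwegian and UK
  cohorts respectively.
* **Confounding**: a single standard-normal latent `U` acts on exposure
  (`confounder_effect_x`, default 1 kg/m²/SD) and log-hazard
  (`confounder_effect_y`, default 0.1); it is emitted as an observed
  column so adjustment experiments can use it. One latent is the simplest
  structure that produces confounded observational associations.
* **Exposure moments**: mean 27, SD 4.5 kg/m², matched exactly in-sample.
* **Survival**: Weibull baseline on the age timescale (default shape 8,
  scale 95 years — adult all-cause mortality of a realistic order), with
  the causal curve (`dose_linear`, `dose_quadratic`, `dose_jshape`;
  parameterised relative to 25 kg/m²) plus confounder and a male-female
  log-hazard gap (`sex_effect_y`, default 0.4) entering proportionally.
  Event times are exact inverse-transform samples conditional on survival
  to a uniform entry age (default 40–70), censored administratively at 85
  — so proportional hazards holds by construction and the generator is
  analytically checkable. The default J-shape (minimum 25, slopes ∓0.05)
  mirrors the qualitative curve debated in the literature; its magnitudes
  are free parameters, not empirical claims.
* **Selection**: optional logistic participation in age (centred at the
  mid entry age), sex, confounder and exposure (centred at its mean).

What the generator does *not* emulate — linkage disequilibrium, genotype
file formats, competing risks, family structure, measurement error in the
exposure, time-varying exposures — bounds what passing tests show: they
validate the statistical machinery under the model's own assumptions, not
robustness to the full messiness of real cohort data.

## Study conditions used by the package's checks

Simulation scale was set so the full suite runs on a desktop: parameter
recovery uses 20 cohorts of n = 100 000 with 100 strata under a linear
log-hazard slope of 0.03 per kg/m² (heterogeneity 1); test calibration
uses 500 cohorts of n = 20 000 with 20 strata under the same truth. The
method-contrast experiment uses n = 50 000, 50 strata, heterogeneity 6,
confounder effects (2, 1) and a null causal effect — under these
conditions the residual method's linearity test rejects (spuriously, at
p ~ 10⁻³–10⁻²) while the doubly-ranked test does not, and the
instrument-strength profile is flat across residual strata but rises
threefold-plus across doubly-ranked strata, although the generator is
identical.

The participation-bias experiment deserves a note on design. With age as
the analysis timescale, selection on baseline age alone cannot bias the
hazard-scale estimate (risk sets compare individuals at identical
attained ages), and selection on sex alone induces bias an order of
magnitude below Monte-Carlo noise at desk scale. The demonstrable and
practically relevant mechanism is selection on a predictor of the
*outcome* jointly with a descendant of the score: the experiment
therefore selects on (age, sex, confounder, exposure) with coefficients
(−0.02, −0.5, −2.5, −0.5) at n = 50 000 and `confounder_effect_y = 0.8`,
treating the confounder as observed. Bias is measured for each seed as
the difference between the estimate on the selected sample and the same
estimator on the complete cohort — a paired anchor valid under any
configured dose-response. Adjusting for the observed selection
predictors shrinks the mean absolute bias about threefold; adjusting for
age and sex only, with selection operating through the unobserved
confounder, leaves a bias whose confidence interval excludes zero.

## Degenerate inputs and numerical choices

Fractional powers require positive exposures, so grids and stratum means
are validated; curve variance terms are floored at zero against rounding;
weighted least squares uses a rank-revealing QR and skips singular
candidate bases; ties in the linearity statistic are truncated at zero
before the χ² reference. Monotone Cox likelihoods are flagged
(`nonconvergent`) and the stratum excluded with a logged reason rather
than reported with an unusable SE. All randomness — genotypes, tie
breaks, trimming, removals — flows through seeds stored in the config,
the assignment and the fit, and rerunning a fit reproduces its report
bundle byte-for-byte.

## Known limitations

LACE estimates average over individuals within a stratum; a non-linear
curve can reflect changing stratum composition rather than a non-linear
individual-level effect. The linearity test's χ²(1) reference ignores
power selection; the trend test treats estimated SEs as known — both are
mildly anti-conservative, as quantified above. The delta-method SE
ignores denominator noise and weak-instrument ratio bias, which matters
if per-stratum instruments are weak (per-stratum F well below 10). No
competing-risks machinery is provided: cause-specific mortality is
handled by censoring non-cause events upstream. Harmonisation of effect
alleles against external weight files is assumed done; only a declared
effect-allele column is carried through.
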