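# stratamr

Stratified non-linear Mendelian randomisation for individual-level cohort
data with a survival outcome.

## The problem

Standard Mendelian randomisation (MR) uses genetic variants as instrumental
variables to estimate a population-averaged causal effect of an exposure
(such as body mass index) on an outcome (such as all-cause mortality). When
the question is the *shape* of the causal relationship — for instance
whether low BMI is itself harmful — the population must be stratified by
exposure level, and stratification is where the danger lies: conditioning
on the exposure, a common effect of the instrument and the confounders,
induces collider bias.

`stratamr` implements the two stratification schemes used for this problem
and everything downstream of them:

* **Residual method** — stratify on `x − E[x | g]`, the exposure residual
  from regressing the exposure `x` on the genetic score `g`. Valid only
  under a *constant genetic effect* assumption: the instrument must shift
  everyone's exposure equally.
* **Doubly-ranked method** — rank by `g` into consecutive prestrata of size
  `Q`; within each prestratum, send the k-th smallest exposure to stratum
  `k`. Requires only the weaker *rank-preserving* assumption and is robust
  to instrument effects that vary across the exposure distribution.

Within each stratum `s` the package estimates a **localised average causal
effect (LACE)** as a ratio of coefficients,

    LACE_s = beta_gy(s) / beta_gx(s),

where `beta_gy` is the log hazard ratio per SD of score from Cox
proportional-hazards regression with attained age as the timescale (left
truncation at study entry, Efron ties) and `beta_gx` the least-squares
slope of exposure on score, both adjusted for the same covariates. The
LACE series is then meta-regressed on the stratum mean exposures using the
analytic derivative of **fractional polynomials** of degrees 1 and 2
(powers from {−2, −1, −0.5, 0, 0.5, 1, 2, 3}, `x^0 ≡ ln x`), inverse
variance weighted, and the dose-response curve `h(x) − h(x_ref)` is
reconstructed with pointwise 95% bounds (reference 25 kg/m²). Linearity
(likelihood-ratio against the linear model) and trend (weighted
meta-regression slope) tests summarise the evidence for non-linearity.
Because doubly-ranked estimates are sensitive to the exact analytic
sample, analyses can be repeated while removing a few individuals at
random each time and combined by **Rubin's rules**. Instrument-validity
diagnostics (per-stratum associations of the score with competing risk
factors such as age and sex) and a scripted participation-selection bias
experiment round out the pipeline.

A synthetic cohort generator (`simulate_cohort()`) reproduces the
statistical structure this analysis assumes — a weighted polygenic score
explaining ~2% of exposure variance, optional monotone heterogeneity of
the instrument effect, confounding, a configurable causal dose-response on
a Weibull hazard, uniform study entry with administrative censoring, and
an optional logistic participation model — so every stage is testable
without access to individual-level cohort data.

## Worked example

```r
library(stratamr)

ch <- simulate_cohort(sim_config(n_individuals = 30000,
                                 dose_response = dose_jshape(),
                                 heterogeneity = 2, seed = 42))
fit <- nlmr(survival::Surv(entry_age, exit_age, event) ~ exposure | score,
            data = ch, q = 30,
            covariates = ~ age_at_baseline + I(age_at_baseline^2) + sex,
            seed = 1)
summary(fit)
#> Non-linear Mendelian randomisation (doubly_ranked stratification)
#>
#> Strata: 30 of 30 used | n = 30000
#> Instrument-exposure slope, top/bottom stratum ratio: 3.14
#>
#> Fractional polynomial (degree 2), powers (-2, -1), curve relative to 25 kg/m^2:
#>      Estimate Std. Error      z Pr(>|z|)
#> x^-2   905.27     882.31  1.026    0.305
#> x^-1   -83.63      66.63 -1.255    0.209
#>
#> Weighted log-likelihood: 28.977 | heterogeneity Q: 36.11
#> Linearity test p = 0.716 | trend test p = 0.687
```

The cohort was generated with a J-shaped causal curve (minimum at
25 kg/m², slopes ∓0.05 per kg/m² on the log-hazard) and an instrument
whose effect on the exposure is three times stronger at the top of the
distribution than at the bottom — the `3.14` ratio printed above is the
pipeline detecting exactly that. At this sample size the linearity and
trend tests do not reject: with ~400 events per stratum, individual LACE
estimates are noisy (standard errors ≈ 0.13–0.19 on the log hazard ratio
scale), so the mild J-shape is not distinguishable from a flat or linear
effect — the central power limitation of stratified MR. The reconstructed
curve is still available:

```r
predict(fit, newdata = c(20, 25, 30, 35))
#>   exposure    estimate        se       lower     upper
#> 1       20 -0.02157354 0.1733080 -0.36125089 0.3181038
#> 2       25  0.00000000 0.0000000  0.00000000 0.0000000
#> 3       30  0.11496744 0.0716052 -0.02537617 0.2553111
#> 4       35  0.24635321 0.1361610 -0.02051736 0.5132238
plot(fit)             # curve with grey 95% CI lines
effect_evident(fit$curve)  # exposure ranges where both bounds slope one way
```

`coef()`, `vcov()`, `fitted()`, `residuals()`, `predict()` and `plot()`
behave as for other fitted-model classes; `write_nlmr_report()` exports
the stratum estimates, curves and a run manifest.

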