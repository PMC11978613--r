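# mdjm — joint models for longitudinal mammographic density and breast-cancer risk

`mdjm` is an R package for studying how longitudinal mammographic
tissue composition relates to the risk of incident breast cancer.  It
is aimed at biostatisticians and epidemiologists who work with
screening-cohort data: repeated mammograms per woman (dense and
nondense tissue areas in cm²), baseline questionnaire covariates (BMI,
HRT use, family history, menopausal status, parity), and follow-up to a
breast-cancer diagnosis on the age time scale with delayed entry.

The scientific difficulty the package addresses is that nondense area
(NDA), dense area (DA) and BMI are strongly interdependent, drift with
age, and are measured with error at irregular visits.  A Cox model on
baseline values, or even a counting-process Cox model with time-updated
values, treats these *endogenous* covariates as error-free step
functions and can mislead.  The package therefore implements the full
comparison ladder:

| Model | Description |
|-------|-------------|
| 1 | Cox, baseline √NDA and √DA (continuous), adjusted for BMI, HRT, family history |
| 2 | Cox, baseline NDA and DA in full-sample tertiles, same adjustment |
| 3 | Extended Cox, counting-process rows with last-value-carried-forward markers |
| 4 | Bivariate joint model for the NDA and DA trajectories |
| 5 | Trivariate joint model adding a longitudinal BMI submodel |

At the core (models 4–5) is a multivariate joint
longitudinal–survival model with shared random intercepts: for marker
*k* of woman *i*,

    y_ik(t) = x_ik(t)'β_k + b_ik + ε_ik(t),      b_i ~ N(0, Σ_b),

with natural-spline (df 5) age effects on the √cm² scale, unstructured
within-visit residual covariance Σ_ε, and hazard

    λ_i(t) = exp( s0(t)'ω + w_i'γ + Σ_k α_k [x_ik(t)'β_k + b_ik] ),

a natural-spline (df 5) log baseline hazard on the age scale, left
truncation at the entry age, and the expected-value association: the
hazard loads on the current model-implied marker level, not the noisy
measurement.  `exp(α_k)` is the hazard ratio per unit of the
transformed marker.  Estimation is direct marginal maximum likelihood:
the random-intercept integral collapses analytically to one dimension
(the longitudinal factor is conjugate Gaussian, and the hazard touches
`b_i` only through `α'b_i`), which is then handled by adaptive
Gauss–Hermite quadrature with analytic gradients for all parameter
blocks.  The test suite verifies the likelihood against brute-force
grid integration to 1e−6.

A calibrated synthetic-cohort generator (`synthetic_config`,
`generate_cohort`) emulates the structure of a large Swedish screening
cohort — entry ages 40–74, ~2-year visit gaps, at most 8 mammograms,
7.9 years of follow-up, ~2.5% events, NDA–DA correlation ≈ −0.506,
NDA–BMI correlation ≈ 0.696 — so that every estimator can be validated
by parameter recovery without access to any real data.  See the
vignette (`vignettes/joint-density-models.Rmd`) for the model details,
calibration constants and design decisions.

## Worked example

```r
library(mdjm)

cohort <- generate_cohort(synthetic_config(n_subjects = 2000, seed = 42))
cohort
#> Synthetic screening cohort: 2000 women, 8358 mammograms, 56 events

reverse_km_median_followup(cohort$subjects)$median
#> [1] 7.9

m1 <- fit_cox(cohort, "baseline_continuous")
m1$hr_rows[1:2, ]
#>     term estimate     HR ci_low ci_high       p
#>  sqrt_nd  0.06336 1.0654 0.9132   1.243 0.42040
#>   sqrt_d  0.10059 1.1058 0.8901   1.374 0.36361

m4 <- fit_joint_model(cohort, "joint2")
m4
#> Joint longitudinal-survival model (joint2), n = 2000, events = 56
#> log-likelihood: -26152.957
#> corr(b): -0.616  corr(eps): -0.425
#> ...
#>            term estimate     HR ci_low ci_high       p
#>        alpha.nd  0.04104 1.0419 0.8554   1.269 0.68342
#>         alpha.d  0.13853 1.1486 0.8654   1.524 0.33755
```

The cohort was generated with true association hazard ratios 1.059
(NDA) and 1.158 (DA) per √cm², random-intercept correlation −0.63 and
residual correlation −0.43; the joint fit recovers the correlations
closely even at n = 2000, while the association estimates carry wide
intervals because only 56 events occurred.  `run_analysis()` executes
any subset of the five models on the full cohort and on the
postmenopausal / premenopausal-under-50 subgroups and assembles a
single results table; `recovery_experiment()` repeats
simulate-and-refit cycles and reports bias, empirical and model-based
standard errors and confidence-interval coverage.

A thin command-line interface is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/mdjm.R", package="mdjm"))')" \
    simulate --n 5000 --seed 1 --out cohort_dir
```

with `fit` and `analyze` subcommands operating on `subjects.csv` /
`visits.csv` files.

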