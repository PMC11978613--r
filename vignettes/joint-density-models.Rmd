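---
title: "Joint models for longitudinal mammographic density and breast-cancer risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint models for longitudinal mammographic density and breast-cancer risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdjm)
```

## The scientific problem

Whether the amount of nondense (adipose) breast tissue visible on a
mammogram is a risk factor, a protective factor, or irrelevant for
breast cancer has been debated for two decades, with published
estimates pointing in both directions.  One methodological explanation
for the disagreement is that nondense area (NDA), dense area (DA) and
body mass index (BMI) are tightly interrelated, all drift with age, and
are measured repeatedly with error, while most published analyses used
a single baseline measurement and a standard Cox model.  A Cox model
with time-updated covariates does not fix this: mammographic areas are
*endogenous* time-dependent covariates, measured with error at
irregular visits, so the counting-process assumption of a fully known
step-function covariate path is wrong in a way that can bias the
estimated association.

`mdjm` implements the modeling ladder that makes this concrete — two
baseline-only Cox models (continuous and tertile-categorized), an
extended Cox model with last-value-carried-forward covariates, and
bivariate/trivariate joint longitudinal–survival models — together with
a synthetic screening-cohort generator calibrated so that every
estimator can be validated by parameter recovery.

## The joint model

For woman $i$, marker $k$ (NDA and DA on the $\sqrt{\mathrm{cm}^2}$
scale; optionally BMI on its raw scale) observed at ages $t_{ij}$:

$$y_{ik}(t) = x_{ik}(t)^\top \beta_k + b_{ik} + \varepsilon_{ik}(t),$$

where $x_{ik}(t)$ contains an intercept, a natural cubic spline in age
with five degrees of freedom, and baseline covariates (BMI, HRT status,
family history; missingness kept as explicit factor levels).  The
random intercepts $b_i = (b_{i1},\dots,b_{iK})$ are multivariate normal
with unstructured covariance $\Sigma_b$; within-visit residuals are
multivariate normal with unstructured covariance $\Sigma_\varepsilon$,
independent across visits.  Random slopes are deliberately excluded:
between-subject heterogeneity in slopes is negligible for these markers
over a follow-up of this length, and intercept-only random effects are
what make the estimation strategy below exact.

The hazard of a breast-cancer diagnosis, on the **age** time scale with
delayed entry at the screening entry age, is

$$\lambda_i(t) = \exp\Big(s_0(t)^\top \omega + w_i^\top \gamma +
  \sum_k \alpha_k \, \mu_{ik}(t)\Big),
  \qquad \mu_{ik}(t) = x_{ik}(t)^\top\beta_k + b_{ik},$$

with $s_0$ a natural spline (df 5, own knots from the event ages) for
the log baseline hazard, $w_i$ the baseline survival covariates, and
the *expected value* association: the hazard depends on the current
model-implied marker level, not on the noisy measurement.  In the
trivariate model the BMI trajectory replaces baseline BMI in $w_i$.
$\exp(\alpha_k)$ is the hazard ratio per unit of the transformed marker
($\sqrt{\mathrm{cm}^2}$ for the areas, kg/m$^2$ for BMI); this scale is
recorded in the fit metadata because hazard ratios for such models are
not comparable across transformation choices.

### Estimation: an exact reduction to one dimension

The marginal likelihood integrates the product of the longitudinal
Gaussian densities and the survival factor over $b_i$.  Two structural
facts make this cheap and accurate:

1. The longitudinal factor times the Gaussian prior is itself Gaussian
   in $b_i$, so it collapses in closed form to a normalizing constant
   times $N(b_i; m_i, V_i)$ — the classic conjugate update.  Visits
   with an unrecorded marker (BMI at most follow-up visits) simply
   contribute the marginal density of the observed markers; the update
   uses the corresponding sub-blocks of $\Sigma_\varepsilon$.
2. Because the random effects are intercepts, the hazard depends on
   $b_i$ only through the scalar $a = \alpha^\top b_i$, and the
   survival factor is
   $\exp\{\delta_i(\eta_i(T_i) + a) - e^{a}\Lambda_{0i}\}$ with
   $\Lambda_{0i}$ a fixed Gauss–Legendre integral of
   $\exp(\eta_i(u))$ over (entry, exit].

The $K$-dimensional integral therefore reduces *exactly* to a
one-dimensional integral in $a$ under $N(\alpha^\top m_i,
\alpha^\top V_i \alpha)$, evaluated by adaptive Gauss–Hermite
quadrature (default 7 nodes) centered and scaled at the mode of the
integrand, found by a safeguarded Newton iteration (the integrand is
always log-concave).  The `gh_nodes` option controls this rule;
`gl_nodes` (default 15 during fitting, 30 for the standalone
cumulative-hazard function) controls the Gauss–Legendre rule for
$\Lambda_{0i}$.  The test suite verifies the whole construction against
brute-force dense-grid integration over $b$ to $10^{-6}$.

Optimization is quasi-Newton (BFGS) with analytic gradients for every
parameter block (chain rule through the conjugate update and the
posterior moments of $a$), a two-stage start (multivariate mixed model
ignoring survival, then the spline-hazard survival submodel at
$\alpha = 0$), and log-Cholesky parameterization of $\Sigma_b$ and
$\Sigma_\varepsilon$ so positive definiteness is unconditional.  A fit
is declared converged only when the relative log-likelihood change is
below $10^{-8}$ and the gradient infinity-norm is below $10^{-3}$;
anything else is flagged, never silently returned.  Standard errors
come from the numerically differenced Hessian of the marginal
log-likelihood at the optimum (central differences of the analytic
gradient).

### Left truncation

Women enter the risk set at their screening entry age.  The survival
factor uses $\Lambda_i(\text{entry} \to T_i)$ only, conditionally on
$b_i$ — the standard delayed-entry treatment in shared-random-effects
software.  A full marginal correction (renormalizing by the probability
of surviving from age 40 to entry given $b$) is a possible alternative;
it differs only when the association and pre-entry hazard are large,
and the conditional variant is the one whose recovery properties the
test suite verifies (estimates are unbiased under the generator, whose
sampling is itself conditional on being event-free at entry).

## The comparison models

* **Model 1** — Cox regression on baseline $\sqrt{\text{NDA}}$ and
  $\sqrt{\text{DA}}$, adjusted for BMI, HRT and family history, age
  scale, delayed entry, Efron ties.
* **Model 2** — as model 1 with the raw-scale areas categorized into
  tertiles.  Cut points are the 1/3 and 2/3 sample quantiles
  (interpolation quantile definition, `type = 7`), always computed on
  the **entire** analysis sample (also for subgroup analyses), with
  left-closed assignment intervals; a joint 2-df Wald test for the NDA
  tertile terms and an optional 9-cell NDA-by-DA grid are reported.
* **Model 3** — the extended Cox model: the visit history is expanded
  into counting-process rows (start, stop] with marker values carried
  forward from the most recent mammogram.
* **Models 4/5** — the bivariate and trivariate joint models above.

Cox fitting, the reverse Kaplan–Meier follow-up summary (censoring
treated as the event; log–log Greenwood intervals) and conditional
logistic regression are delegated to the `survival` package; the
partial likelihood is additionally implemented directly (Efron ties,
delayed entry) and checked against explicit risk-set enumeration and
against `coxph`.  A nested case–control design with incidence-density
sampling (default 2 controls per case, matched on entry age within
±2.5 years; both configurable, as the matching details of the design
being emulated are not fully specified) feeds the conditional logistic
fit.

## The synthetic cohort generator

The generator emulates the structure of a large Swedish mammography
screening cohort; its defaults are a fixed calibration, not tuning
knobs:

* **Entry ages** 40–74, a two-component truncated-normal mixture
  (weights 0.43/0.57, means 44.5/61, SDs 3/6) calibrated to a median
  entry age of 54 and, through a latent age at menopause
  $N(51, 3^2)$ with a 1.3-year perimenopausal window, to 56.1%
  postmenopausal and 40% premenopausal women.
* **Visit gaps** log-normal with `meanlog = log(1.997)`,
  `sdlog = 0.2005`, at most 8 visits, stopping at age 74 or at the
  administrative follow-up limit (7.9 years).  The realized median gap
  is 1.97 years.  The printed interquartile interval this emulates
  (1.61–2.11) is left-skewed — the median sits near the upper quartile
  — which no two-parameter log-normal can match, so the calibration
  prioritizes the median and the IQR *ratio*; the simulated IQR is
  (1.72, 2.26).
* **Markers** are generated from the joint model itself:
  $\sqrt{\text{NDA}}$ with level 11.9 at age 55, +0.565 per BMI unit
  and a mildly concave rising age trend; $\sqrt{\text{DA}}$ with level
  4.5, −0.075 per BMI unit and a falling trend; BMI around 24.5 with a
  slight rise.  Random-intercept SDs (1.84, 1.30, 3.60), residual SDs
  (1.0, 0.8, 1.0), intercept correlation −0.63 and residual correlation
  −0.43 for (NDA, DA).  Raw areas are stored as the squares of the
  simulated $\sqrt{}$-scale values (floored at zero, which is rare
  under the calibration).  Baseline BMI *is* the BMI-marker observation
  at the entry visit, so the covariate and the trajectory are mutually
  consistent; follow-up BMI is recorded with probability 0.3 per visit,
  emulating the limited BMI follow-up of the emulated study.  These
  constants jointly reproduce the published raw-scale correlations
  (NDA–DA −0.506 over all mammograms, NDA–BMI 0.696 at baseline).
* **Events** are drawn by inverting the joint-model cumulative hazard
  (Gauss–Legendre quadrature inside a bisection to $10^{-10}$), with a
  log-linear baseline (level $-7.73$ at age 55 before covariate and
  marker contributions, slope 0.045/year), association
  hazard ratios fixed at the published point estimates (bivariate
  truth: 1.059 for NDA and 1.158 for DA per transformed unit;
  trivariate truth: 1.030, 1.149, plus 0.04 per kg/m$^2$ for the BMI
  trajectory — the BMI association is not published and 0.04 is a
  plausible postmenopausal value), and survival covariate effects of
  realistic size (e.g. log 1.57 for family history).  This yields
  about 2.5% events over follow-up, matching the emulated cohort's
  incidence.  Administrative censoring is a fixed 7.9-year per-subject
  window rather than a calendar clock — calendar dates are out of
  scope, so follow-up summaries on the duration scale are compressed
  relative to a registry cohort with longer register-based follow-up.

What the generator does **not** emulate: mammogram images and
measurement pipelines, informative dropout between screens (attendance
stops only at event/censoring), competing risks (death is censoring),
calendar-period effects, and the skewness of real BMI (the marker model
is Gaussian; the simulated BMI IQR is symmetric where the real one is
mildly right-skewed).  Passing recovery tests therefore demonstrates
the estimators are correct *under the stated model*, not that the model
is correct for any particular cohort.

## Numerical choices and degenerate inputs

* Knots: interior knots at equally spaced quantiles of the observed
  visit ages (boundary at the 1st/99th percentile clipped to [40, 74]);
  the baseline-hazard basis takes its knots from the event ages
  instead.  Knot sets are serialized in every fit for reproducibility.
* Σ matrices that drift toward singularity during optimization are
  handled by rejection (the objective returns a large value) rather
  than ad-hoc ridging; a region guard (|packed parameter| ≤ 50) stops
  quasi-Newton line searches from entering regions where catastrophic
  cancellation would corrupt the objective.
* When $\alpha^\top V_i \alpha < 10^{-12}$ the association integral is
  evaluated in closed form instead of by quadrature.
* Ties: Efron approximation throughout the Cox side; simulated ages are
  continuous so ties occur with probability zero.
* Degenerate schedules (one visit, zero follow-up) are legal inputs
  everywhere; a tertile request on fewer than three distinct values, a
  visit after exit, an orphan visit id, or a negative raw area is a
  data error that names the offending rows.

## Validation scale

The test suite validates the likelihood against dense-grid integration
on toy subjects, the spline basis against a truncated-power
construction, the Cox partial likelihood against hand-enumerated risk
sets and `coxph`, the event sampler against its closed-form exponential
special case, and parameter recovery at cohort sizes of 600–1500
subjects with 4–10 replicates; the acceptance script reruns recovery at
10 replicates of n = 1000 and n = 1500 (bivariate) and 8 replicates of
n = 800 (trivariate, 5 quadrature nodes).  These sizes are chosen so a
complete validation runs on a laptop in minutes while keeping the
Monte-Carlo error of the recovery averages a fraction of the published
effect sizes; correlations recover to two decimals at these sizes,
while association hazard ratios carry Monte-Carlo noise of a few
percent because a 2.5% event rate yields only 20–40 events per
replicate.

## Known limitations

* Only linear ("expected value") association structures are
  implemented — no current-slope or cumulative associations, no cure
  fraction, no competing risks, no dynamic prediction.
* The left-truncation correction is conditional on $b$ (see above).
* The trivariate model treats within-visit residual correlation as the
  only cross-marker residual dependence; residuals are independent
  across visits by assumption.
* Standard errors for derived quantities (e.g. the random-intercept
  correlation) are not delta-method propagated; recovery experiments
  assess them by replicate spread instead.
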