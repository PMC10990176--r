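---
title: "Methods: trait/state panel models for kinesiophobia and physical activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trait/state panel models for kinesiophobia and physical activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinpanel)
```

## The model and its assumptions

The package studies two processes observed at four occasions (weeks 1, 3, 6
and 12 after cardiac hospital discharge): a kinesiophobia questionnaire
total (13 items scored 1–4, totals 13–52) and total physical activity in
minutes per day. The central estimator is a path-model (SEM) engine in the
reticular-action (RAM) formulation: a model is a node set with directed
coefficient entries `A`, symmetric disturbance (co)variances `S` and
intercepts `M`; with `T = (I - A)^{-1}` the implied covariance over the
observed selection is `F T S T' F'` and the implied mean `F T M`. Two
substantive models are built on top of this engine.

**Random-intercept cross-lagged panel model (RI-CLPM).** Each observed
score is grand mean + stable between-person random intercept + fluctuating
within-person component. The random intercepts are latent variables whose
loadings on their repeated measures are all fixed to 1; within components
carry the dynamics: per transition, two autoregressive paths (carry-over
within a process) and two cross-lagged paths (spill-over between
processes), plus free residual variances. The model assumes multivariate
normality (the ML estimator is normal-theory), linear wave-to-wave
dynamics, and discrete occasions — the unequal calendar spacing of the
waves is deliberately ignored, matching the design being emulated;
continuous-time reparameterisation is out of scope.

**Trait + AR(1) alternative.** Kinesiophobia is reduced to a pure random
intercept (a trait with occasion-specific noise, no autoregression), while
activity is an observed AR(1) chain without a random intercept. The two
processes connect only through free within-wave covariances between the
kinesiophobia residual and the activity disturbance — the association
parameter must exist in the model for its nullity to be a finding.

## The degrees-of-freedom reconstruction

The published fit tables pin the two models to 12 and 20 degrees of freedom
against the `p(p+3)/2 = 44` sample moments of `p = 8` observed variables,
but do not list the free-parameter inventory. The builders here are the
reconstructions consistent with those counts:

* `build_riclpm()`: 8 means + 2 random-intercept variances + 1
  random-intercept covariance + wave-1 within variances/covariance (3) +
  per-transition 2 autoregressive + 2 cross-lagged paths and 2 residual
  variances (18) = 32 free parameters, hence df = 12. The textbook variant
  that also frees the within-wave residual covariances at waves 2–4 gives
  df = 9; it is available via
  `riclpm_options(dynamic_residual_covariances = TRUE)` but is not the
  default because it contradicts the printed df.
* `build_ri_ar()`: 8 means + 1 trait variance + 4 occasion residual
  variances + 1 wave-1 activity variance + 3 autoregressive paths + 3
  activity residual variances + 4 concurrent covariances = 24 free
  parameters, df = 20. Dropping the concurrent covariances
  (`concurrent_covariances = FALSE`) raises df by 4.

Whether the original fits constrained lagged paths or residual variances to
equality across transitions is unknowable from the tables; the defaults
leave them free per transition, consistent with distinct printed
coefficients per transition.

```{r df}
model_df(build_riclpm())
model_df(build_ri_ar())
```

## Estimation and numerical choices

`fit_ml()` minimises the normal-theory discrepancy
`F = log|Sigma| - log|S| + tr(S Sigma^{-1}) - p + (m - mu)' Sigma^{-1} (m - mu)`
with BFGS, using an analytic gradient derived from RAM trace identities.
Specific choices:

* **Chi-square multiplier**: `(n-1) F` (Wishart ML) by default; an `n`
  switch exists because software conventions differ and are not always
  documented.
* **Start values**: observed variances and means seed free variances and
  means (a latent variance starts at half the variance of an observed node
  reached through fixed unit loadings); paths and covariances start at 0.
  Optimizer coordinates are rescaled by per-node SD proxies (covariance
  entries by `s_i s_j`, paths by `s_i / s_j`, means by `s_i`) so
  questionnaire-scale and minutes-scale parameters are comparably
  conditioned.
* **Convergence**: scaled gradient norm below 1e-6, with up to 5 seeded
  jittered restarts; a fit that stalls above 1e-4 is flagged
  non-converged, never silently returned.
* **Infeasible iterates**: a non-positive-definite implied covariance
  returns a barrier value and the line search backs off (step halving by
  the optimizer's own mechanism).
* **Uncertainty**: standard errors from the inverse numerical Hessian of
  `F` scaled by `2/(n-1)`; standardized coefficients multiply each path by
  `SD(source)/SD(target)` from the implied covariance extended over latent
  nodes, with delta-method intervals. Variance estimates are not bounded
  away from zero, so small-sample fits can produce near-singular
  information; such standard errors are flagged `NA` rather than invented,
  and multiple-imputation pooling then uses the imputations with finite
  uncertainty.
* **Fit indices**: CFI and TLI against the independence baseline
  (`Sigma = diag(S)`, closed form). Untruncated values are reported
  alongside the conventional truncation to `[0, 1]`; a saturated model
  (df = 0) flags them undefined.

## Missing data

`littles_mcar()` estimates the grand mean and covariance by EM over
missingness patterns (absolute log-likelihood change below 1e-8 or 500
sweeps) and compares pattern-wise observed means against the EM estimates;
the statistic is referred to chi-square with `sum_j p_j - p` degrees of
freedom. `fcs_impute()` is full conditional specification with the
Bayesian normal-linear kernel — the standard chained-equations kernel for
continuous data; the original analysis names only the method and its
software, not the kernel, `m`, or iteration counts, so defaults are
`m = 20` and 10 cycles and are recorded in every run log. Rubin's rules
(`rubin_pool()`) combine per-imputation estimates; chi-square/CFI/TLI have
no consensus pooling rule and are reported as across-imputation means with
their spread, labelled as such in the output.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` reproduces the design quantities of the emulated study:
the exclusion flow (188 assessed, 2 died, 149 questionnaire completers, 33
accelerometer non-wearers, 116 analysed), four waves at weeks 1/3/6/12,
wave-level questionnaire missingness rates (22.8, 24.8, 28.2, 36.2%),
epoch-level accelerometer missingness (14.4% — the published total does not
say whether it is epoch-, day- or week-level; the generator exposes it at
epoch level), and the published wave medians as grand means (TSK 27.4 →
25.0; total activity 82.1, 127.5, 127.0, 123.9 minutes/day). Spreads
convert printed IQRs to normal SDs (IQR/1.349 ≈ SD), split roughly evenly
between trait and state variance, consistent with the published
standardized trait loadings of 0.63–0.81. Default lagged coefficients are
the published standardized estimates converted to raw scale under the
wave-1 within SDs, with residual variances keeping within variances
approximately stationary.

Deliberate simplifications, which bound what passing tests say about real
data: disturbances are multivariate normal (questionnaire totals are
integer-valued and mildly skewed in reality); missingness is MCAR only
(dropout in real cohorts is plausibly selective); epoch MET values are
uniform within their intensity band; daily activity targets are constant
within a week (linearly interpolated between waves), so there is no
day-of-week structure; there is no wear-time compliance behaviour and no
demographic effects on the latent processes. Questionnaire totals are
generated continuously, then rounded and clamped to 13–52 before item
disaggregation — the rounding noise is part of the synthetic model, since
the emulated analysis treats the total as continuous.

Other generator conventions: epochs default to 1 minute; the wear period
defaults to 90 days with a 14-day "desk" preset for fast runs; activity
category shares per wave follow the published category medians with a
Dirichlet perturbation (concentration 60) so categories sum exactly to the
total.

## Measurement conventions

MET cut-points are printed as "<3", "3–6", ">6" without boundary
ownership; here moderate owns both boundaries (the closed interval [3, 6])
so the three labels partition the line. A sedentary cut-point (default 1.5
MET) below which epochs are not activity at all is a package addition —
without it, resting time would count as light activity; it is configurable
because the emulated device's internal convention is unknown. Week windows
are consecutive 7-day blocks from the discharge day; a week with no
available days yields a missing value, never zero. The activity variable
entering the models is the light+moderate+heavy total.

## Descriptive statistics

Spearman correlations use average ranks with Fisher-z intervals (variance
`1.06/(n-3)`) and magnitude bands small ≤ 0.30 < medium ≤ 0.50 < large on
the absolute value. The signed-rank test handles zero differences by the
Pratt convention and computes its exact null by convolution over doubled
average ranks for up to 25 nonzero differences (equivalent to enumerating
all sign assignments, but feasible at that size); beyond that, a normal
approximation with the rank-based variance and continuity correction. The
independent-groups comparison (used for subgroup columns of a
characteristics table, where the emulated report does not name its test)
is a rank-sum test, exact in the tie-free small-sample case — it is
labelled a reconstruction in the pipeline output. Median/IQR use
linear-interpolation quartiles by default; the rule is switchable and
logged because printed medians are rule-sensitive.

## Effect-size labels

Standardized coefficients are labelled small below 0.30, moderate in
[0.30, 0.50), large at or above 0.50; the conventional print bands leave a
gap between 0.29 and 0.30 which is closed downward.

## Problem sizes used in validation

The test suite validates the machinery at sizes chosen to balance
Monte-Carlo resolution against runtime, as this package's own convention:
moment fidelity of generator versus engine at n = 200,000 draws within 3
Monte-Carlo standard errors entrywise for 5 randomized admissible parameter
sets; parameter recovery at n = 10,000 within 3 reported standard errors;
chi-square calibration over 200 replicates at n = 500; MCAR test size over
500 replicates at n = 300 and power over 100 replicates at n = 1,000;
imputation interval coverage over 200 replicates of a bivariate design at
n = 2,000; and null cross-lag interval coverage over 100 replicates at the
emulated study's own n = 116, mirroring its null finding as a property
rather than a number.

## Known limitations

The engine fits complete-data sample moments; rows with missing cells are
dropped unless imputed first (full-information ML is out of scope — the
emulated analysis imputed first, too). No robust or scaled test
statistics, no bootstrap intervals, no multi-group or measurement
invariance machinery, at most two processes. Variance parameters are
unconstrained, so boundary-adjacent truths can yield inadmissible
(negative-variance) solutions at small n; these surface through
convergence flags and `NA` standard errors rather than being truncated.
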