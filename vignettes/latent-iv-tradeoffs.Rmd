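---
title: "Latent-variable trade-off models with model-implied instrumental variables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent-variable trade-off models with model-implied instrumental variables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latentiv)
```

## The scientific problem

Tests of somatic trade-offs — for example whether nutritional investment in
the brain competes with investment in lean body tissues or fat — face three
linked inferential threats. Simple size measurements (organ volumes, tissue
masses) are error-prone proxies for the construct of interest, *nutritional
investment*; unmeasured confounders and possible reverse causation make
ordinary regression slopes causally inconsistent; and observational cohorts
are often small. `latentiv` implements the estimation strategy suited to
this setting: a structural equation model with multiple-indicator latent
variables, estimated equation by equation with **model-implied instrumental
variables and two-stage least squares (MIIV-2SLS)**.

The packaged model (`eth_model()`) encodes a two-latent brain/body design.
A latent "nutritional investment in brain tissues" emits three indicators —
total intracranial volume (TIV, the scaling indicator), cerebrum and
cerebellum volumes — and a latent "nutritional investment in lean body
tissues" emits summed organ volumes (scaling indicator) and skeletal muscle
mass. Height adjusts both latents and measured fat mass for body size, and
the causal paths of interest run from the brain latent to the body latent
and to fat mass:

```{r model}
eth_model()
```

## The model and the estimator

The measurement model links each indicator $\gamma$ to its latent $\eta$:

$$\gamma_i = \alpha_i + \lambda_i \, \eta + \varepsilon_i,$$

with one indicator per latent fixed at $\lambda = 1$ (and $\alpha = 0$) to
give the latent its unit. The latent-variable model stacks the structural
equations, e.g. $\eta_{body} = \alpha + \beta_1 \eta_{brain} + b\,height +
\zeta$. Errors are mutually uncorrelated unless declared otherwise with the
`a ~~ b` syntax.

Estimation proceeds in the four MIIV-2SLS steps:

1. **Specification** — the model grammar above, parsed by `parse_model()`.
2. **Latent-to-observed transform** (`miiv_transform()`) — every latent is
   replaced by its scaling indicator minus that indicator's error;
   intercepts and loadings are conserved. Each non-scaling measurement
   equation and each structural equation becomes an observed-variable
   regression whose error is a *composite disturbance*, e.g. for the body
   equation $\zeta_{body} + \varepsilon_{organs} - \beta_1
   \varepsilon_{TIV}$.
3. **Instrument search** (`eligible_miivs()`, `select_miivs()`) —
   instruments are found among the model's own observed variables.
4. **2SLS with diagnostics** (`fit_miiv_sem()`) — each equation is
   estimated from centred moment matrices,
   $b = (S_{xz} S_{zz}^{-1} S_{zx})^{-1} S_{xz} S_{zz}^{-1} S_{zy}$,
   with Sargan overidentification tests, Holm adjustment across the
   equation family, and a BCa bootstrap for uncertainty.

### Instrument eligibility is decided symbolically

A candidate instrument must have *structurally zero* model-implied
covariance with the equation's composite disturbance. The package expands
every observed variable, by iterative substitution of the structural and
measurement equations, into exogenous sources plus error terms, and
requires the expansion to share no error term (directly or through a
declared error covariance) with the disturbance. Two deliberate choices:

* The expansion is carried out in the **original latent system**, so exact
  algebraic cancellations are honoured. Substituting the brain latent into
  the fat equation introduces $-\beta_2\varepsilon_{TIV}$ into that
  equation's disturbance, but the same term enters with opposite sign
  through the scaling indicator, and fat's reduced form contains no
  $\varepsilon_{TIV}$ at all. Fat mass is therefore a valid instrument for
  the body equation — confirmed numerically in the test suite by
  brute-force simulation at $n = 10^6$ — and this is what makes a
  two-degree overidentification test available for every overidentified
  equation of the packaged model.
* Eligibility is never decided from sample covariances: sampling noise must
  not change the instrument set.

Only recursive (acyclic) structural models are supported, and an equation's
outcome is never its own instrument.

### Instrument selection

With a moderate sample one should not use every eligible instrument.
Following the two-more-than-needed rule, each equation receives
`#regressors + overid_degree` instruments (default `overid_degree = 2`).
Exogenous regressors always instrument themselves; the remainder are chosen
by greedy forward selection on the first-stage $R^2$ computed from the
moment matrices. Where an equation has several endogenous regressors the
greedy step maximises the **minimum** $R^2$ increment across their first
stages — protecting the weakest first stage — with ties broken by model
registry order. The selection log is kept in the fit object so the choice
is auditable. If fewer eligible instruments exist than the target, all are
used and a warning is recorded; fewer instruments than regressors is an
error.

### Sargan tests and the Holm family

For an overidentified equation the Sargan statistic is $n R^2$ from the
regression of the 2SLS residual on all the equation's instruments, computed
in **centred** moment algebra, on $df = |z| - |x|$ with a chi-square upper
tail. Exactly identified equations have no test: their p-value is NA and
they are excluded from the Holm step-down family (the family size counts
only defined p-values). Holm adjustment itself is delegated to
`stats::p.adjust`.

## Missing data: the two-stage moment route

The default `missing = "twostage"` estimates the saturated means and
covariances by an EM algorithm under multivariate normality and feeds those
moments to the estimator, with `n_effective` equal to the total row count.
Numerical choices: covariances use denominator $n$ (the ML convention, so
the EM and complete-data branches agree exactly); EM stops when successive
observed-data log-likelihoods change by less than `1e-8`, and failure to
converge within 500 iterations is an error, not a warning. On complete data
one EM step reproduces the sample moments to machine precision. A
`"listwise"` option reproduces the usual sensitivity analysis;
`run_tissue_analysis()` reports both fits side by side.

## Bootstrap design

`bootstrap_bca()` resamples rows with replacement and refits the whole
pipeline per replicate, with two design decisions:

* **Instrument sets are frozen** at the original selection, so every
  replicate estimates the same estimand; re-selecting per replicate would
  mix model-selection variability into the standard errors.
* Under the two-stage missing route each replicate **reruns EM**.

Standard errors are the standard deviation over `B` successful replications
(default 5000); failed replicates (singular fits, non-converged EM) are
discarded and redrawn up to `2B` attempts, after which the failure taxonomy
is reported as an error. Intervals are bias-corrected and accelerated: the
bias correction $z_0$ is the normal quantile of the fraction of replicates
below the point estimate (ties counted half, clamped away from 0 and 1),
the acceleration comes from jackknife skewness (leave-one-out moments are
computed by downdating the sufficient statistics on complete data), and
percentiles are read with type-6 quantile interpolation. With extreme
acceleration a BCa interval can fail to bracket the point estimate; that is
recorded as a warning on the fit, never silently repaired. Setting
`bootstrap_B = 0` skips uncertainty entirely (point estimates and Sargan
tests are still produced).

One master `seed` drives everything; sub-streams for the bootstrap (and,
in `run_tissue_analysis()`, for the two fits) are derived from it and
recorded in the result, so reports are byte-identical under a fixed seed.

## The synthetic cohort generator

No individual-level data ship with the package; `simulate_cohort()`
generates cohorts with the statistical structure the analysis assumes, so
that every pipeline stage is testable. The generating mechanism follows the
model equations exactly — height feeds the brain latent, the brain latent
feeds the body latent and fat mass, and latents emit indicators through
intercepts, loadings and independent errors.

Calibration of `cohort_params()` defaults:

* Anchored to the study conditions: $n = 70$; structural paths
  $\beta_{brain \to body} = -0.41$ and $\beta_{brain \to fat} = -0.56$ on
  the analysis scale; height mean 161 cm with CV 4.1%; and 3
  missing-completely-at-random cells on the organs variable.
* Fixture choices: indicator means, loadings and error scales are
  physiologically plausible values for young adult women (TIV ≈ 1400 cm³,
  cerebrum ≈ 1000 cm³, cerebellum ≈ 130 cm³, summed organs ≈ 2100 cm³,
  skeletal muscle ≈ 17 kg, fat ≈ 17 kg, with within-latent indicator
  correlations strongest for cerebrum–TIV and SM–organs). They are *not*
  estimates of any cohort's summary table, and the package's
  parameter-recovery properties do not depend on them.

Paths are expressed on the analysis (rescaled) scale so the calibrated
defaults equal the headline estimates; the generator emits data on the
original measurement scale by inverting the rescale plan.
`implied_moments()` gives the exact closed-form population moments of the
same system, which powers the strongest test in the suite: the estimator
applied to implied moments must return every free parameter to $10^{-9}$.

Two optional departures from the base mechanism exist for calibration
studies: a centred, variance-matched skewed error option (2SLS does not
assume normal errors; the option changes marginal skewness without touching
the implied covariance) and an injectable cross-loading of a given
standardized size, used to measure Sargan power against an omitted
cross-loading.

What the generator does **not** emulate: the real cohort's full empirical
distribution (only its model structure), measurement artefacts such as the
literature-based heart-volume adjustment, non-MCAR missingness, and any
upstream laboratory corrections. Passing tests therefore demonstrate that
the estimator inverts the assumed data-generating process, not that the
assumed process is true of any particular dataset.

## Rescaling

Volume and height variables are divided by 10 or 100 before estimation to
reduce disparities in variance: the packaged model file assigns
TIV and cerebrum 100; cerebellum, organs and height 10. The exact 10-vs-100
assignment per variable is a package default recorded in the model file
header (`#| rescale:` directive) — the assignment follows each variable's
magnitude in its measurement unit. Coefficients are reported on both the
analysis scale and, via the inverse transform, the original scale
(`tidy(fit, scale = "original")`).

Two further conventions worth stating: height predicts the brain latent as
a regression path (not a mere correlation), matching the model diagram's
reading that body size adjusts both latent constructs and fat mass; and
intercepts are always estimated (free) except for scaling indicators, where
the intercept is fixed to 0 so the latent inherits the scaling indicator's
mean as well as its unit.

## Degenerate inputs and numerical edges

Constant columns are rejected before fitting with a named error; singular
instrument moment matrices and singular projected designs are equation-level
errors carrying the equation id; an all-missing column, fewer than three
non-missing values, or a zero-variance column stop the descriptive stages.
`stats::shapiro.test` is defined for 3–5000 observations; outside that
range the descriptives table reports an NA normality p-value with a note.

## Problem sizes used by the test suite

The shipped checks run at sizes chosen to balance Monte-Carlo resolution
against a single-CPU run: population-identity checks are exact and instant;
parameter recovery uses 500 cohorts of $n = 5000$; study-scale behaviour
uses 2000 cohorts of $n = 70$; Sargan calibration uses 2000 cohorts of
$n = 1000$ (power: 300 cohorts); bootstrap coverage uses 300 cohorts of
$n = 500$ with $B = 400$; and the numeric instrument-eligibility oracle
simulates $n = 10^6$ once. The coverage study draws complete cohorts so
that the 120000 bootstrap refits measure interval behaviour rather than EM
runtime; EM-under-bootstrap is exercised separately.

## Known limitations

* Only recursive structural models; no latent interactions, categorical
  indicators or multi-group models.
* System-wide maximum-likelihood SEM is out of scope (the package is the
  equation-by-equation alternative to it), so no global fit indices.
* BCa intervals at small $B$ undercover slightly for heavy-tailed IV
  statistics; the bootstrap default $B = 5000$ is the recommended setting.
* The two-stage missing route assumes multivariate normality of the
  saturated model and MCAR/MAR missingness.

## A worked run

```{r worked, eval = FALSE}
set.seed(1)
cohort <- simulate_cohort(cohort_params(), seed = 42)
report <- run_tissue_analysis(cohort, bootstrap_B = 2000, seed = 7)
report
tidy(report$fit_primary, scale = "original")
autoplot(report$fit_primary)
```
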