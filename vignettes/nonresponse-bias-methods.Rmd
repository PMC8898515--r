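---
title: "Methods: non-response bias and missingness mechanisms in a blocked factorial survey trial"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: non-response bias and missingness mechanisms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Mailed surveys on sensitive topics — here, combat exposure and military
sexual assault among Veterans applying for PTSD disability benefits — suffer
unit non-response that is rarely ignorable. When the people who decline are
systematically different from those who return the questionnaire, every
naive prevalence estimate inherits that selection. `nrbias` implements the
analysis pipeline for a trial design that attacks the problem from two
sides:

1. **Experimentally**: a gender-blocked 3×2×2 factorial randomization of
   cover-letter content (combat / unwanted sexual attention / lifetime and
   military experiences), stated sampling source (a roster of recent-era
   Veterans / a list of disability-benefit applicants), and promised
   incentive ($20 / $40), asking whether any letter composition *prevents*
   biased recruitment.
2. **Analytically**: because the sampling frame carries eight administrative
   flags for every invitee (age < 30, non-white race, combat exposure,
   military sexual trauma, serious mental illness, Charlson index > 0, any
   VA disability benefits, PTSD-specific benefits), non-response bias is
   directly measurable, and the prevalence of the two *self-reported*
   outcomes can be re-estimated under three missingness assumptions and
   compared.

The real trial data are restricted; the package therefore ships a
synthetic-cohort generator with the trial's dimensions (two gender blocks of
480, twelve equal cells of 40 per block) and frame prevalences, plus known
latent outcomes, so that every estimator can be scored against ground truth.

## Bias metric and response rates

For a binary characteristic, non-response bias is the percentage of
respondents carrying it minus the percentage in the full sampling frame
(percentage points; negative = under-representation). Response rates use the
AAPOR definition RR1: returned completed surveys over all assigned units.
Homogeneity across arms is tested with Pearson chi-square on the
stratum × (returned, not returned) table, without continuity correction —
the conventional default; the `correct` flag exposes the Yates version
because the original analysis software default is not documented anywhere we
can check. No multiple-testing adjustment is applied, matching how such
response-rate tables are conventionally reported.

## Variance in bias explained by the manipulations

`factorial_anova_eta2()` asks how much of the variance in bias each factor
explains. The unit of analysis is the respondent-level *frame-centered*
indicator (the binary correlate minus the block's frame prevalence), so each
cell mean equals that cell's bias and the ANOVA partition of the indicator
is a partition of bias variance. η² for a factor is 100·SS(factor)/SS(total).

Two details are genuinely open and were fixed as follows:

* **Interaction pooling.** Interactions are tested highest-order first; any
  with p ≥ 0.05 are pooled into the error term (their df are added to the
  error df) and the model is refit. This is the conventional reading of
  "non-significant interaction terms added to the final model's error term".
  The threshold is exposed (`pool_alpha`); `pool_alpha > 1` keeps every
  interaction, and the sum-of-squares identity Σ SS(terms) + SS(error) =
  SS(total) holds either way (it is asserted to 1e-8 relative in the tests).
* **Sum-of-squares type.** Sequential (type I) sums of squares in the fixed
  canonical order content, source, incentive. For the *assigned* cohort the
  design is exactly balanced, where all SS types coincide; among respondents
  the design is only approximately balanced, and the sequential partition is
  the one that keeps Σ SS = SS(total) exactly, which the η² construction
  requires.

With a single two-level factor, η²/100 reduces to the squared point-biserial
correlation, and under a null design the expectation of η² is
df(factor)/(n−1); both are used as independent oracles in the tests.
Cohen's *h* (`cohen_h()`) is provided as the effect-size helper for
proportion differences.

## Prevalence under three missingness assumptions

For each self-reported outcome the package produces a mechanism triplet:

* **MCAR** — `prevalence_mcar()`: the complete-case mean among responders.
* **MAR** — `impute_mar()`: multiple imputation (default m = 25). The
  imputation model is a logistic regression of the outcome on the
  frame-complete covariates (all eight administrative flags, plus the four
  arm dummies when an assignment is supplied), fit among responders. Each
  imputation draws coefficients from the fit's asymptotic normal
  approximation (a proper posterior-draw step; `draw = "bootstrap"` refits
  on a resample instead), then draws Bernoulli outcomes for every
  non-respondent. Prevalences are pooled by Rubin's rules with the
  per-imputation sampling variance p(1−p)/N on the proportion scale:
  total = within + (1 + 1/m)·between, asserted to 1e-10 in the tests.
* **MNAR** — `fit_em_nonignorable()`: a selection model
  P(y|x; β)·P(r|x, y; α, γ) with logistic links and the outcome entering
  the response model linearly through γ (γ = 0 nests the ignorable case).
  The observed-data likelihood is maximized by EM. E-step: each
  non-respondent's posterior probability of y = 1 given their covariates
  *and the fact that they did not respond*. M-step: weighted logistic fits
  on the expanded table (responders at weight 1; each non-respondent as two
  pseudo-rows weighted by the posterior). `prevalence_mnar()` averages
  observed outcomes for responders with the posterior weights for
  non-respondents (the default; `type = "marginal"` uses the model-implied
  P(y=1|x) instead — both are provided because reports of this method rarely
  state which was used).

The diagnostic logic is triangulation: numerically close estimates and a
small variance across the three assumptions support random missingness; a
large spread is evidence that the missingness mechanism matters. The summary
follows the convention of such tables: the variance across the three
estimates is a sample variance (denominator 2) on the *proportion* scale,
while the estimates and the max−min range are in percent — which is why
variances print like 0.0144 next to ranges like 22.5.

### Numerics of the weighted logistic core

Both the MI model and the EM M-steps go through one IRLS (Fisher scoring)
routine, `fit_weighted_logistic()`, written here because the M-steps need
arbitrary nonnegative fractional case weights, fractional responses, warm
starts, and deterministic behavior. It is validated three ways: against a
brute-force likelihood grid search on small instances (to 1e-4), against
`glm()` on weighted problems (to 1e-8), and by the exact equivalence of a
row duplicated at half weight with a single unit-weight row. Likely
separation (coefficients still growing at the iteration cap) is flagged and
warned; the MI responders model falls back to a small ridge penalty in that
case, with a logged message. Variances come from the inverse Fisher
information at convergence.

### EM acceleration

The textbook EM iteration for this model is reliable but slow near its
optimum (hundreds to thousands of iterations at n in the tens of
thousands). The fitter therefore applies squared extrapolation (SQUAREM
-type) by default: two EM steps define an extrapolated candidate, one
further EM step stabilizes it, and whenever the candidate would *decrease*
the observed-data log-likelihood the plain double EM step is used instead.
The recorded log-likelihood trajectory is therefore non-decreasing by
construction — the EM ascent property is asserted (to 1e-10 slack) at every
iteration of every fit in the test suite — and the accelerated and textbook
iterations are verified to reach the same stationary point. Convergence is
declared when the maximum absolute parameter change falls below `tol`
(default 1e-6).

### What identifies γ — and the validation scenarios

Without an instrument (a variable affecting response but not the outcome),
γ is identified purely by the parametric form of the two logistic models.
That identification is real but *weak* when the covariates predict the
outcome poorly: the Fisher information for γ at the truth implies an
asymptotic sd of γ̂ around 0.18 at n = 50,000 when the outcome model's
effects are of size ~1 over five binary covariates — and empirical spread is
larger still, because the likelihood is nearly flat and asymptotics arrive
late. In that regime the MNAR prevalence wanders 1–3 percentage points from
the MAR estimate *even when missingness is truly ignorable*; this is a
property of the maximum-likelihood estimator itself (the EM lands on the
same optimum as a quasi-Newton search of the observed-data likelihood to
all printed digits), not of the implementation.

The method's own stated premise is covariates "known to be associated with
the outcome". The frozen validation scenarios therefore live in that
strong-prediction regime — administrative-flag-to-self-report odds ratios of
roughly 4–20, which is realistic for an administrative flag and a
self-report of the same construct — where the Fisher sd of γ̂ drops to
~0.08 and the three estimators agree to within a percentage point under
ignorable missingness:

* `em_recovery_scenario()` — data generated from the selection model itself
  (the strong-prediction outcome model, an all-nonzero response model,
  γ = −1) for parameter-recovery checks at n ≈ 5,000 over 200 replicates.
  The scenario was validated with a direct maximum-likelihood oracle before
  being frozen: a quasi-Newton search of the observed-data likelihood
  started at the truth recovers all parameters with under ~3% median bias
  there, so failures would implicate the EM, not the estimand. In weaker
  scenarios (outcome effects of size ~1, ~55% missingness) the same oracle
  shows 14–15% median bias on γ and the response intercept — the MLE's own
  finite-sample behavior — which is why such scenarios cannot serve as
  implementation tests.
* `mar_benchmark_scenario()` — γ = 0 with response driven by two strong
  outcome predictors at a ~65% return rate (n ≈ 20,000): the complete-case
  mean is biased upward by construction, imputation recovers the latent
  truth, and the selection model should show no *systematic* discrepancy
  from imputation. Because a single replicate's MNAR−MAR difference still
  carries Monte-Carlo noise of sd ≈ 0.7 pp, the equivalence checks compare
  the median signed discrepancy over several fixed-seed replicates.
* `mcar_benchmark_scenario()` — an intercept-only response model at the
  trial's 42.7% rate (n ≈ 50,000) for the full three-way coherence check.

Notably, one *very* strong binary predictor does not help: with only two
covariate cells, γ remains confounded with the intercepts. What identifies
γ is a wide spread of the outcome logit across many cells.

Reports carry a standing caveat that MNAR estimates are
assumption-contingent scenarios, not assumption-free corrections.

## The synthetic cohort: what it does and does not emulate

`trial_scenario()` fixes the generator at the trial's conditions: blocks of
480, equal cells of 40, the frame prevalences of the study population
(e.g. 67.1% administrative combat exposure among men, 45.6% military sexual
trauma among women), marginal response rates solved to the study's 41.5%
(men) and 44.0% (women), arm effects set from the reported response-rate
contrasts (claims-list and $40 effects for men, $40 for women), and a
nonignorable response process with the study's signature: combat-exposed
subjects respond more, male assault survivors respond less. Latent
self-reports are generated for *every* frame member — responders and not —
which is what makes estimator recovery scorable. Administrative military
sexual trauma and self-reported military sexual assault are deliberately
distinct variables linked only through the outcome model, since the
administrative flag also covers severe physical sexual harassment.

Default covariates are independent Bernoullis at the frame prevalences; a
Gaussian-copula threshold construction (`dependence`) induces pairwise
association when a scenario needs MAR missingness to be nontrivial. A
positive-definiteness check rejects impossible association structures at
spec time.

Features of real data the generator does **not** emulate — and which
passing tests therefore say nothing about: item (within-questionnaire)
non-response, reminder-wave dynamics, misclassification in the
administrative flags, within-household clustering, and any response process
outside the logistic selection family. The generator's response model *is*
the family the MNAR estimator assumes, so MNAR recovery results here are
best-case by construction; that is exactly what makes them a test of the
implementation rather than of the model.

## Problem sizes and determinism

The test suite runs the recovery study at n ≈ 5,000 × 200 replicates, the
ignorable-equivalence check at n ≈ 20,000 × 5 replicates, and the MCAR
coherence check at n ≈ 50,000 × 3 replicates — sizes at which the relevant
Monte-Carlo errors are a comfortable factor below the assertion bounds.
Every stochastic step takes an explicit integer seed; stage sub-seeds are
derived deterministically from one master seed and recorded in the run
manifest, and re-running a pipeline configuration reproduces every output
file bit-for-bit. Percentages are carried at full precision internally and
rounded only at report time (rates, biases, estimates and ranges to one
decimal; cross-mechanism variances to four).

## Known limitations

* MNAR estimates rest on an untestable parametric assumption; with weakly
  outcome-predictive covariates they are close to unidentified, and the
  package reports (rather than hides) non-convergence and separation in
  small strata.
* Per-stratum mechanism triplets inside `mechanism_table()` use the
  administrative correlates only (arm dummies are partially constant within
  an arm stratum); the overall column additionally adjusts for arm.
* The ANOVA treats respondents as independent; the "logistic, mixed-models"
  style of bias analysis is out of scope.
* No survey weighting, post-stratification or propensity adjustment is
  implemented; the design measures bias rather than correcting it.
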