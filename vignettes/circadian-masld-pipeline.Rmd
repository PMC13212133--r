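---
title: "Circadian rest-activity amplitude and MASLD: methods and design"
author: "circMASLD maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circadian rest-activity amplitude and MASLD: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

circMASLD implements an end-to-end epidemiological and proteomic pipeline
linking disruption of the rest-activity circadian rhythm to metabolic
dysfunction-associated steatotic liver disease (MASLD): circadian metrics
from 24-hour activity profiles, MASLD phenotyping, crude and adjusted
association models, a moderated-t differential-abundance screen, a
per-protein causal mediation screen, and L1-penalized biomarker panel
selection with multi-classifier evaluation. Because the cohort data this
kind of analysis is usually run on are access-restricted, the package
ships a synthetic-cohort generator with planted ground truth, so every
stage is exercisable and testable at desk scale.

# Circadian metrics

Each participant contributes 24 hourly mean accelerations (hour of day,
averaged over the wear period). M10 and L5 are the mean activity over the
most active 10-hour and least active 5-hour windows; relative amplitude is

$$\mathrm{RA} = \frac{M10 - L5}{M10 + L5} \in [0, 1].$$

Design choices:

* **Windows wrap across midnight.** The least active 5 hours commonly
  straddle midnight; a non-wrapping search would bias L5 upward. All 24
  circular start hours are searched for both window lengths, and the
  search is tested against an exhaustive brute-force oracle.
* **Window statistic is the mean** of hourly values. Means and sums give
  identical RA for fixed window lengths; the mean keeps the original
  units.
* **Ties** between equally active windows are broken by the smallest
  start hour, making results deterministic.
* **Low-RA group**: participants more than two sample standard deviations
  below the sample mean RA (strict `<`); participants exactly at the
  threshold are "high". The multiplier is a parameter
  (`classifyLowRA(..., sdMultiplier)`) with default 2.

# Phenotyping

Hepatic steatosis uses the fatty liver index,
$\mathrm{FLI} = 100\,\sigma(0.953\ln TG + 0.139\,BMI + 0.718\ln GGT +
0.053\,WC - 15.745)$, with the conventional cutoff of 60. The
coefficients are unit-bound (TG in mg/dL, GGT in U/L), so explicit
converters (`tgToMgdl()`, 1 mmol/L = 88.57 mg/dL) are provided for
cohorts reporting SI units; a wrong-unit input cannot be detected from
the values themselves and is documented as a caller responsibility.

MASLD is steatosis plus at least one of: type 2 diabetes; BMI >= 25
kg/m^2; or at least two of six metabolic-abnormality criteria (insulin
resistance, prediabetes, low HDL, hypertriglyceridemia, hypertension,
elevated waist circumference, with sex-specific HDL and WC cutoffs). Two
judgment calls are worth stating. First, "metabolic abnormality" is read
as *at least two* of the listed criteria, the standard cardiometabolic
reading. Second, unknown insulin resistance counts as *not met* rather
than missing, so the criterion count is a lower bound and the diagnosis
is conservative toward non-MASLD.

The composite sleep score awards one point per low-risk behaviour (early
chronotype, 7-8 h sleep, no insomnia symptoms, no snoring, low daytime
sleepiness); scores >= 4 / 2-3 / <= 1 map to healthy / intermediate /
poor patterns. Durations are questionnaire integers; non-integer input
is floored with a warning so the short/normal/long categories partition
all values.

# Association models

The 2x2 odds ratio uses the Wald construction,
$\mathrm{CI} = \exp(\ln OR \pm 1.96\,SE)$ with
$SE = \sqrt{1/a + 1/b + 1/c + 1/d}$, because that is the arithmetic the
printed intervals this package's tests check against actually follow.
The Haldane-Anscombe +0.5 correction is applied only when a zero cell
exists, keeping the headline estimate exact otherwise.

Multivariable models are binomial GLMs with logit link, fitted by
iteratively reweighted least squares (`stats::glm`, tolerance 1e-8, at
most 100 iterations), with Wald standard errors. Perfect separation is
detected from collapsing fitted probabilities plus exploding standard
errors and reported as `converged = FALSE`. The model ladder fits four
nested covariate sets (crude; + age, gender; + education, ethnicity,
deprivation; + glucose, drinking, smoking). Reference levels — gender
female, education College, ethnicity White, smoking and drinking Never —
are a documented convention, configurable by releveling before the call.
Missing covariates are imputed by median (continuous) or mode
(categorical, ties to the lexicographically smallest level), with audit
indicator columns; the method is deliberately simple because nothing in
the analysis depends on imputation subtleties.

# Differential abundance

Per protein, a two-group mean contrast gives the log-scale fold change
and pooled residual variance on $n-2$ degrees of freedom. Variances are
then shrunk toward a shared prior estimated by matching the first two
moments of $\log s^2_g$ to the scaled-F sampling model (digamma/trigamma
equations, Newton inversion of the trigamma function):

$$\tilde{s}^2_g = \frac{d_0 s_0^2 + d_g s^2_g}{d_0 + d_g},$$

with the moderated t referred to a t distribution on $d_0 + d_g$ degrees
of freedom. When the observed variances show no spread beyond sampling
noise the prior degrees of freedom are capped at 1e6 and every moderated
variance collapses to the prior (the plain mean of observed variances).
The implementation is cross-checked against limma's `squeezeVar` in the
test suite, which serves as an independent oracle only. Multiplicity is
handled by Benjamini-Hochberg (Bonferroni available); the DEP cutoff is
adjusted p < 0.05 with no fold-change filter, both configurable, and the
common DEP set is the intersection of the low-RA and MASLD contrasts.
Proteins with more than 20% missing values are dropped, the rest
mean-imputed per protein, before any testing.

The per-protein model is a plain two-group contrast without covariates;
covariate-adjusted contrasts were considered and left out of the default
because the mediation stage re-models every candidate with the full
covariate set anyway.

# Mediation

For one protein, the mediator model is a linear regression of abundance
on exposure and covariates; the outcome model is a logistic regression of
MASLD on exposure, mediator and covariates. Effects are computed on the
outcome-probability scale by plug-in g-computation: with
$\hat m_i(x')$ the predicted mediator under exposure regime $x'$,

$$p(x, x') = \tfrac1n \sum_i \sigma\!\big(\hat\beta_0 + \hat\beta_x x +
\hat\beta_m \hat m_i(x') + \hat\beta_c^\top c_i\big),$$

ACME averages the mediator contrast over both exposure arms, ADE the
exposure contrast over both mediator regimes, and the decomposition
$\mathrm{total} = p(1,1) - p(0,0) = \mathrm{ACME} + \mathrm{ADE}$ holds
exactly. Uncertainty is a nonparametric bootstrap of participants
(default 1000 resamples; percentile intervals; two-sided percentile
p-value floored at $1/n_\mathrm{boot}$). The bootstrap was chosen over
quasi-Bayesian coefficient draws for transparency: every resample is a
full refit of both models. Per-protein seeds derive deterministically
from a root seed and the protein's index, so screens are reproducible
protein by protein.

One calibration property deserves emphasis. The ACME estimate is
essentially a product of two regression coefficients, and the behaviour
of its bootstrap p-value depends on which null holds. Under the single
null — no exposure-mediator path but a real mediator-outcome effect —
the p-values are approximately uniform, and the test suite verifies this
over hundreds of seeded replicates. Under the *complete* null (both
paths zero, the situation of a pure-noise protein) the product estimator
concentrates near zero faster than its bootstrap spread suggests and the
percentile p-values are conservative, piling up near 1. This is the
long-known behaviour of product-of-coefficients mediation tests, not an
implementation artifact; practically it means the ACME p < 0.05 screen
over-controls, never inflates, its false-positive rate on noise
proteins, and the suite asserts exactly that.

The proportion mediated is ACME/(ACME+ADE) at the point estimates, on
the risk-difference scale, and is deliberately not clamped: opposing
direct and indirect effects can push it outside [0, 1], and such
proteins simply fail (or trivially pass) the > 0.10 screen; the screen
combines it with the ACME p < 0.05 filter. Both filters are applied
together, before panel selection — the alternative ordering
(proportion filter after the LASSO) was considered and rejected because
panel selection should only see proteins with a defensible mediation
signal. The exposure is the binary low-RA indicator; a continuous
exposure can be passed instead, since `mediate()` only assumes a 0/1
contrast for its two regimes.

# Panel selection and evaluation

Candidates passing the mediation screen enter an L1-penalized logistic
regression. Features are standardized internally (parameters stored for
prediction); the lambda grid is 100 log-spaced points running four
decades down from $\lambda_{\max}$ (the smallest lambda zeroing every
coefficient); lambda is chosen at the *minimum* mean cross-validated
binomial deviance over ten outcome-stratified folds — not the 1-SE rule,
because the minimum-CV rule is the procedure this pipeline defines. The
optimization is delegated to glmnet; an independent proximal-gradient
(ISTA) optimizer in the test suite confirms the selected nonzero set and
coefficients on a small problem.

Nonzero proteins are ranked by decreasing absolute standardized
coefficient (ties by id). For each panel size k an unpenalized logistic
model on the top-k proteins is fitted on the 70% training split and its
AUC evaluated on the held-out 30% — held-out rather than training CV, to
avoid optimism in the size-selection curve. The parsimony rule picks the
smallest k whose AUC is within 0.01 of the curve's maximum. The final
panel is then refitted with four classifiers behind a common
fit/predict-probability contract: in-package logistic regression,
random forest, gradient-boosted trees, and an RBF support-vector machine
with Platt-style sigmoid probability calibration. The tree and kernel
learners delegate to randomForest, xgboost and e1071 — the package's
contribution is the selection and evaluation procedure, not those
learners — with fixed documented defaults (500 trees; 100 boosting
rounds at depth 3, learning rate 0.1; C = 1, RBF gamma = 1/p).

ROC/AUC uses the Mann-Whitney rank statistic with midrank tie handling;
the curve thresholds at every distinct score so its trapezoidal area
equals the rank AUC to machine precision, and both identities (strictly
increasing score transforms leave AUC unchanged; negating scores
complements it) are asserted in tests.

# Enrichment and networks

Functional context is strictly offline: over-representation is an
upper-tail hypergeometric test of a query set against user-supplied GMT
collections with BH adjustment across sets, and hub detection takes the
top 10% of nodes by degree on a user-supplied edge list (duplicate edges
and self-loops removed), including all nodes tied with the k-th degree so
the result is independent of input ordering. Live pathway or interaction
databases are version-dependent and deliberately out of scope.

# The synthetic cohort

The generator emulates the *statistical structure* the pipeline assumes,
not any particular dataset:

* **Activity**: 24-hour cosinor profiles,
  $\max(0, \mathrm{mesor} + A\cos(2\pi(h - \phi)/24) + \varepsilon)$,
  mesor 28, acrophase 14 h, hourly noise SD 2 (arbitrary
  milli-gravity-like units, order-of-magnitude plausible for wrist-worn
  accelerometry rather than calibrated to any cohort). The zero clip
  reflects nonnegative acceleration and slightly attenuates RA at high
  amplitude.
* **Exposure**: a latent binary group (probability 0.05, matching the
  few-percent prevalence a mean-minus-2-SD rule produces in practice)
  with cosinor amplitude drawn from the lower or upper quarter of
  `amplitude_range` (default 6-24). The generator drives the proteome
  and outcome with this *binary latent group* rather than the continuous
  amplitude: with a continuous exposure, the "planted ACME" of the
  downstream binary low/high analysis has no closed ground truth,
  whereas the binary group keeps every planted mediation effect exactly
  computable by g-computation on the true models. Continuous variation
  in RA remains through the amplitude jitter within each regime.
* **Proteome**: mediator proteins are `a * group + N(0,1)` (default
  a = 0.6); all others independent standard normal.
* **Outcome**: logistic with intercept -1.3, direct effect 0.3,
  protein effects b = 0.5 on each of 6 mediators, plus standardized age,
  sex and BMI effects (0.3, 0.6, 0.8), giving roughly one-third MASLD
  prevalence. The defaults keep each mediator's planted proportion
  mediated near `ab / (c + k·ab)` ≈ 0.14 — comfortably above the 0.10
  screen; with many equal mediators that proportion shrinks toward zero,
  which is a structural fact about shared pathways worth remembering
  when configuring `n_mediators`.
* **Covariates** are generated independently (age normal, sex Bernoulli,
  BMI/TG/GGT lognormal, and so on) — the simplest structure that
  exercises adjustment; real cohorts have correlated covariates,
  measurement error, batch structure and missingness patterns the
  generator does not emulate, so green tests here demonstrate
  correctness of the procedures, not robustness to real-data pathology.
* **Seeding**: one root seed expands into per-component substreams
  (covariates, group, profiles, proteome, outcome), so enlarging the
  proteome never perturbs the covariate draws.

# Numerical choices and problem sizes

GLM fits converge at relative deviance change 1e-8 (100 iterations
max); the trigamma inversion runs Newton to 1e-8; LASSO uses glmnet's
default convergence threshold; bootstrap p-values are floored at
1/n_boot. Degenerate inputs have defined behaviour throughout:
constant mediators and single-class labels are errors, constant LASSO
features are dropped with a warning, empty DEP or candidate sets stop
the pipeline gracefully with a stage name and message rather than an
error.

The shipped tests and the acceptance script run the recovery studies at
n = 5000 participants with 50-500 proteins and 200-400 bootstrap
resamples, and the end-to-end pipeline at n = 3000 with 300 proteins —
sizes chosen so the full suite completes in minutes on one core while
keeping every stage's power high enough for planted-truth recovery.

# Known limitations

Sequential ignorability is assumed, not probed (no sensitivity
analysis); mediators are screened one at a time, so co-mediated paths
load partly on the direct effect; exposure-mediator interactions are not
modelled; the per-protein DE contrast is unadjusted by default; and the
synthetic generator's independence assumptions understate the
collinearity of real cardiometabolic covariates.
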