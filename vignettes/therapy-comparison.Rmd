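---
title: "Comparing oral antidiabetic therapies in observational cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing oral antidiabetic therapies in observational cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oadcompare)
```

## The setting and the estimand

`oadcompare` targets a common real-world design in diabetes health-services
research: a prospective cohort of type-2 diabetes patients on oral agents,
followed over four quarterly waves, with no restriction on discontinuation,
switching, or add-on of drugs. Eight therapy arms are compared — the five most
prevalent monotherapies (metformin, Xiaoke Pill, other herbal TCMs,
gliclazide, acarbose), glibenclamide (kept despite its small size because it
is the chemical substance of the Xiaoke Pill), Xiaoke Pill combinations, and
a pooled "Others" arm — on seven outcomes: an endpoint glycemic-control
indicator (HbA1c strictly below 6.5%), a 0–4 hypoglycemia incidence count
(one report per follow-up wave), the endpoint EQ-5D utility, and three cost
components plus their total in 1000-RMB units.

The estimand for each arm is the population-average potential outcome: the
mean outcome the cohort would have shown had everyone used that therapy.
Identification rests on conditional independence given the observed baseline
covariates — a rich but finite set, so residual confounding is always
possible; the package's job is to make the adjustment machinery correct and
testable, not to certify the assumption.

### Arm definitions

The intent-to-treat (ITT) assignment is the plan observed at baseline: a
singleton plan of one of the six named agents keeps its own arm, any plan of
two or more agents containing the Xiaoke Pill is "Xiaoke Pill+", and
everything else — including all remaining monotherapies and combinations — is
"Others". The on-treatment cohort keeps a patient only when all four
follow-up drug sets equal the baseline set. We read "without discontinuation,
switching, or add-on" strictly, as set equality at every wave; a patient who
dropped a drug for one quarter and resumed it is excluded. This is the
conservative choice; a laxer rule would only enlarge the sensitivity cohort.

### Covariates

All 35 control variables are 0/1 indicators. Categorical variables enter as
dummy groups with the reference level encoded as all-zero (age < 50, primary
education, Beijing, lowest income band, URBMI insurance, duration < 5 years).
Continuous measurements are dichotomized at clinically conventional cutoffs:
BMI ≥ 24 (the Chinese overweight threshold), baseline HbA1c < 6.5% and
fasting glucose < 7 mmol/L (control targets), SBP ≥ 140 / DBP ≥ 90 mmHg
(hypertension), TC ≥ 5.2 and TG ≥ 1.7 mmol/L (dyslipidemia), EQ-5D ≥ 0.9.
All cutoffs use `>=` (or `<` for the control-type indicators) so boundary
values are classified deterministically; missing baseline values are an
error, never imputed (the analysis cohort is complete-case by definition).

## The estimators

**Unadjusted summaries.** Per-arm means with `sd/sqrt(n)` errors
(binomial `sqrt(p(1-p)/n)` for the binary endpoint). Pairwise arm contrasts
use two-sample z-tests on the estimates and their standard errors, unadjusted
for multiplicity by default — the convention of the tables this mirrors — with
Bonferroni available via `pairwise_z_pvalues(adjust =)`. Whether a pooled or
per-arm variance underlies such published tables is usually unstated;
per-arm standard errors are used throughout because they remain valid under
heteroskedasticity across arms.

**Compact letter display.** Two arms share a letter iff their pairwise p-value
is at or above the level. Letters are built by insert-and-absorb: start from
one letter covering all arms; each significant pair splits every column
containing both members into two (one without each member); duplicate and
subset columns are absorbed. The construction guarantees the iff property for
any, including non-transitive, significance patterns, and the test suite
verifies minimality against a brute-force clique-cover enumeration for up to
five arms. Columns are ordered by first arm for determinism.

**OLS predictive margins.** Every outcome — including the binary indicator and
the count — is fit by the same linear model on arm dummies plus the 35
indicators, reproducing the published modeling choice; the arm coefficients
are then adjusted mean differences versus metformin. Margins are computed by
G-computation (set every patient's arm, predict, average), which for a linear
model collapses to the prediction at the average design row; consequently
`margin(k) − margin(ref)` equals the arm coefficient exactly and the margins
with no covariates are exactly the subgroup means — both identities are
asserted to 1e-10 in the tests. Standard errors use the delta method with the
full coefficient covariance, treating covariate means as fixed (the standard
predictive-margins convention). Classical homoskedastic errors are the
default; an HC1 robust option exists (`robust = TRUE`) but is not used in the
headline tables since the source tables' errors are reproducible under the
classical form.

**Inverse probability weighting.** Propensities come from one multinomial
logit of arm on the 35 indicators. Arms below 30 patients are merged into
"Others" first — a ~12-patient arm cannot support its own propensity
equation — with the threshold configurable. The likelihood is maximized to a
relative tolerance of 1e-12 (up to 1000 iterations), and coefficient
divergence beyond ±15 on the logit scale is reported as separation with the
offending covariates named. Weights are `1/P(observed arm)`, Hájek-normalized
within arm; the weighted-mean standard error uses the linearization variance
of the ratio estimator, `sqrt(Σ w²(y−ŷ)²)/Σw`. Symmetric percentile
truncation is available but off by default, matching an analysis that reports
no extreme-weight handling; probabilities below 1e-6 are a hard error.

**Double selection.** The candidate pool is the 35 mains plus the interaction
of each remaining indicator with the baseline-glycemic-control indicator —
squared terms of dummies duplicate the mains and are excluded — giving
exactly 69 columns after deterministic deduplication. For each outcome, one
adaptive lasso is run with the outcome as response and one per non-reference
arm with the 0/1 arm indicator as response; OLS margins are refit on the
union of the selections. Choices the method description leaves open, and how
this package resolves them:

* *Pilot weights*: OLS coefficients on standardized columns, `γ = 1`
  (weights `|β̂|⁻¹`), with a ridge-initialized pilot when OLS is
  rank-deficient.
* *Penalty tuning*: "empirical BIC" is implemented as the Gaussian
  `n log(RSS/n) + df log(n)` with `df` = number of nonzero coefficients,
  minimized over the coordinate-descent path (tolerance 1e-7); ties break
  toward the sparser model.
* *Treatment equations*: linear (least-squares) working models for the 0/1
  arm indicators rather than logistic lasso — deterministic, fast, and
  sufficient for selection; run per arm, not jointly on the arm block.
* Penalty factors are pre-normalized to sum to the column count so that the
  backend's internal rescaling is inert; on an orthonormal design the
  solution then matches closed-form soft-thresholding exactly, which the
  tests exploit as an oracle.

Selection is invariant to column order and to affine rescaling of the
response (columns are standardized and the response centered internally).

## The synthetic cohort generator

The generator emulates the study conditions rather than any convenient test
case: 1903 patients; covariate prevalences equal to the whole-sample
prevalences of the real cohort (e.g. 49% hypertension, 39% baseline glycemic
control, five cities with Beijing at 17%); arm shares matching the observed
therapy distribution (metformin 10.67%, Xiaoke Pill 12.24%, glibenclamide
0.63%); and true per-arm margins set to the covariate-adjusted estimates of
the real study (e.g. control rates 0.33 metformin vs 0.45 Xiaoke Pill, total
costs 8.55 vs 5.34 thousand RMB).

Assignment is multinomial logit with intercepts calibrated so the linear
predictor at the average covariate vector reproduces the target arm shares,
plus confounding coefficients chosen once to mimic the observed imbalance:
herbal TCM users concentrated in Shenyang (+2.2 log-odds) with more heart
disease and longer duration, gliclazide users concentrated in Nanjing, Xiaoke
users with better baseline glycemia and less hypertension, combination users
in Guangzhou with higher income. Setting `confounding = FALSE` zeroes all of
it.

Outcome mechanisms are chosen so the configured margins are the exact
potential-outcome means wherever possible:

* the binary endpoint uses a linear-probability model on mean-centered
  indicators (probabilities clipped to [0.01, 0.99]; a configuration whose
  implied probabilities leave [−0.05, 1.05] is rejected as an error, and the
  default effect sizes — scaled-down versions of the fitted outcome-model
  coefficients — keep all patterns strictly inside). A logistic option exists
  for misspecification experiments;
* hypoglycemia incidence is binomial(4, p) via per-wave Bernoulli flags;
* EQ-5D is Gaussian (sd 0.05) censored into [0, 1]; at the configured means
  (≥ 0.87) the censoring mass is ≈1% and the induced bias ≈2e-4, negligible
  against Monte-Carlo error;
* costs are Gaussian (sds 0.9 / 0.8 / 0.25 thousand RMB) floored at zero, the
  truncated-Gaussian analogue of the linear model actually fit to costs. For
  arms whose mean sits within ~2 sd of zero (glibenclamide inpatient cost,
  0.53), the floor makes the realized mean exceed the configured margin, so
  recovery checks use the glycemic-control endpoint, whose mechanism is
  exact.

Covariates are simulated independently across dummy groups because only
marginal prevalences are published; real covariates are correlated (age with
duration and comorbidity, city with insurance), so the generator understates
collinearity among confounders. Adherence is Bernoulli with probability
878/1903 — the on-treatment fraction of the real cohort — implemented as an
add-on drug from a uniformly chosen wave onward. What passing tests show is
therefore that the estimators are correct *under the assumed structure*
(conditional independence, linear outcome surfaces, independent indicators);
they cannot certify performance under residual confounding or strong
covariate dependence, which no analysis of such data can.

A deterministic `fixture_cohort()` carries the exact published arm counts
(203/233/137/128/110/177/12/903) and city counts (314/440/403/366/380) for
exercising the counting and reporting paths.

## Validation design

The test suite distinguishes identities (asserted to 1e-10 or exactly):
cost-component sums, margins-equal-means, margin-minus-reference equals
coefficient, Hájek invariance to weight rescaling — from statistical
properties, which are checked by simulation at fixed seeds. The central one
is the recovery study (`estimator_recovery()`): 200 replicate cohorts of
1903 patients under the confounded defaults; for each estimator the per-arm
bias is standardized by its Monte-Carlo standard error. With 8 arms × 3
adjusted estimators, requiring every |z| < 2 would fail ~70% of the time for
an exactly unbiased estimator, so the criterion is the aggregate fixed before
any run: mean z² ≤ 2 and max |z| ≤ 4 per adjusted estimator, and
max |z| > 4 for the unadjusted means (whose Other-TCMs bias is ≈ −0.05, an
order of magnitude beyond Monte-Carlo noise at 200 replicates). Oracles are
kept independent of the code paths they check: explicit normal equations for
OLS, a likelihood grid for the multinomial fit, closed-form soft-thresholding
for the adaptive lasso, and exhaustive clique-cover enumeration for the
letter display.

Problem sizes in the default test run — 200 replicates at n = 1903 for
recovery, 50 000 patients for the generator-truth check, 8000 for the
share check — were chosen so each statistical property is tested with
comfortable power while the whole suite completes in a few minutes.

## Known limitations

* All outcomes are modeled linearly, by design fidelity to the source
  analysis; logistic/Poisson alternatives are out of scope.
* EQ-5D utilities are inputs; item-level scoring with a national value set is
  not implemented.
* No doubly robust (augmented IPW) estimator and no debiased-lasso inference;
  the double-selection margins use conventional OLS standard errors, which
  ignore selection uncertainty.
* Cost-effectiveness ratios are not computed; the pipeline stops at per-arm
  cost and effect estimates.
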