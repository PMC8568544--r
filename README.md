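# oadcompare

Multi-arm, real-world comparison of oral antidiabetic therapies on efficacy,
adverse effects, quality of life and cost.

## The problem

Observational cohorts of type-2 diabetes patients choose their own therapy, so
a naive comparison of outcomes across therapy arms mixes treatment effects
with confounding: patients with better baseline glycemia disproportionately
choose some drugs, city of residence drives both drug choice and outpatient
cost, and so on. `oadcompare` implements a complete analysis pipeline for this
setting with eight therapy arms — metformin, Xiaoke Pill (a traditional
Chinese compound of glibenclamide and herbs), other herbal TCMs, gliclazide,
acarbose, Xiaoke Pill combinations, glibenclamide, and a pooled "Others"
category — and four estimators of the per-arm outcome means:

1. **Unadjusted subgroup means** with binomial/empirical standard errors and a
   compact letter display (arms sharing a letter are not significantly
   different at the 5% level).
2. **OLS predictive margins** (G-computation): fit
   `y_i = α + Σ_k τ_k D_ik + x_i'β + ε_i` over the 7 treatment dummies
   (reference metformin) and 35 clinically anchored binary covariates, then
   report `margin(k) = mean_i(ŷ_i | D = k)` with delta-method standard
   errors. For a linear model `margin(k) − margin(ref) = τ_k` exactly, and
   without covariates the margins are exactly the subgroup means.
3. **Inverse probability weighting**: multinomial-logit propensity scores
   `P(D_i = k | x_i)`, Hájek-normalized weights `1/P(observed arm)`, weighted
   arm means with linearization standard errors, and weighted covariate
   balance diagnostics (small arms are merged into "Others" before fitting).
4. **Double-selection adaptive lasso**: build a 69-column candidate pool
   (35 mains + 34 interactions with the baseline-glycemic-control indicator),
   select predictors of the outcome and of each treatment indicator by
   adaptive lasso with BIC-tuned penalty, and refit OLS margins on the union
   of the selections.

Because the motivating survey data are not publicly deposited, the package
ships a synthetic cohort generator ([`generate_cohort()`]) that reproduces the
study's structure — 1903 patients, five cities, confounded multinomial arm
assignment down to a ~12-patient glibenclamide arm, and binary/count/
continuous/cost outcomes with *known* true arm margins — so that every
estimator can be validated against ground truth.

## Worked example

```r
library(oadcompare)

co  <- generate_cohort(sim_config(seed = 7))   # 1903 synthetic patients
arm <- define_cohorts(co)$arm                  # ITT therapy arms
oc  <- derive_outcomes(co)
cv  <- build_covariates(co)                    # 35 binary indicators

subgroup_summary(oc$hba1c_control, arm, type = "binary")
#>   arm               n estimate     se letters
#> 1 Metformin       190    0.342 0.0344 a
#> 2 Xiaoke Pill     229    0.445 0.0328 b
#> 3 Other TCMs      198    0.318 0.0331 a
#> 4 Gliclazide      131    0.389 0.0426 ab
#> 5 Acarbose        113    0.336 0.0444 a
#> 6 Xiaoke Pill+    203    0.478 0.0351 b
#> 7 Glibenclamide    14    0.286 0.121  ab
#> 8 Others          825    0.364 0.0167 a

fit <- fit_outcome_model(oc$hba1c_control, arm, cv)
predictive_margins(fit)
#>   arm           margin     se letters
#> 1 Metformin      0.340 0.0351 a
#> 2 Xiaoke Pill    0.430 0.0321 ab
#> ...
```

The unadjusted Xiaoke Pill control rate (0.445) shrinks toward the configured
true margin (0.45 here, but 0.430 estimated after adjustment in this draw)
once covariates are controlled; the letter groups say which arms remain
distinguishable. `run_pipeline()` executes all four estimators and writes CSV
tables (arm counts, balance, unadjusted outcomes, coefficients, margins, IPW
outcomes, weighted balance, selected covariates, post-selection margins) plus
a JSON manifest.

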