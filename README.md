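# fairaudit

Provenance-based fairness auditing for clinical risk prediction models.

`fairaudit` is built for a common and uncomfortable situation in clinical
machine learning: a risk model (say, for 30-day hospital readmission) may
treat demographic groups differently, and an outcome metric alone cannot
tell you *why*. The package pairs group-fairness statistics with **decision
provenance** — a log of the mechanism behind every prediction — so an
auditor can both detect a disparity and trace it to the model internals
that produced it. Because real audits can rarely be validated (the true
bias in clinical data is unknown), the package includes a cohort simulator
with a *known, injected* gender bias, which makes the whole audit chain
testable end to end.

It is aimed at biostatisticians, ML governance teams and methods
researchers who need a reproducible harness for studying when and how
fairness audits succeed.

## What it computes

Patients carry four clinical features (age, BMI, comorbidity, gender) and
a binary readmission outcome drawn from a logistic data-generating
process

> logit P(Y = 1) = β₀ + β_age·age_z + β_bmi·bmi_z + β_com·C + β_gender·G,

with defaults β₀ = −1.0, β_age = +0.50, β_bmi = +0.40, β_com = +1.00 and
an injected male penalty β_gender = −0.30 (G = 1 for male). Two model
families are audited:

* an **L2-penalized logistic regression** whose provenance records the
  per-feature logit contributions c_j = w_j·x_j (with w₀ + Σc_j equal to
  the logit to machine precision), and
* a **100-tree probability random forest** whose provenance records each
  tree's decision path, vote and the normalized Gini importances, with
  paths replayable from the stored tree structures alone.

On a held-out 70/30 outcome-stratified split the audit computes per-group
selection rates, TPR and FPR, and the two headline disparities (both
female − male):

* **DPD** — demographic parity difference, the gap in selection rates;
* **EOD** — equal opportunity difference, the gap in true positive rates,

with permutation significance (p = (k+1)/(N+1) over N = 1000 random
relabelings of gender), 5-fold stratified cross-validation with t-based
95% confidence intervals, a counterfactual gender-flip analysis of
decision-boundary cases (|p̂ − 0.5| ≤ 0.15), a gender-excluded ablation,
and a sensitivity sweep over β_gender ∈ {−0.10 … −0.80}.

Every result lands in an **AI Fairness Provenance Record (AFPR)**: a
schema-validated JSON document whose inference log is hash-chained with
SHA-256 over a canonical serialization, so any later alteration,
reordering or deletion of a logged decision is detectable.

## Worked example

```r
library(fairaudit)

cohort <- generate_cohort(cohort_spec(seed = 42))        # 1000 patients
split  <- stratified_split(cohort, 0.3, seed = substream_seed(42, "split"))
train  <- cohort[cohort$patient_id %in% split$train_ids, ]
test   <- cohort[cohort$patient_id %in% split$test_ids, ]

model <- fit_logistic(train)
model
#> L2-logistic audit model (C = 1, converged after 5 iterations)
#> (intercept)     age_std     bmi_std comorbidity      gender
#>     -0.6866      0.4300      0.4583      0.9042     -0.5999
```

The fitted gender weight is negative: the model has learned the injected
male penalty. The fairness report quantifies its downstream effect:

```r
fairness_report(test$outcome, predict(model, test), test$gender)
#> Fairness report (n = 300, threshold 0.50)
#>    group   n TP FP TN FN selection_rate   TPR   FPR
#> 1 female 156 27 22 78 29          0.314 0.482 0.220
#> 2   male 144 20  8 85 31          0.194 0.392 0.086
#>   DPD (female - male): +0.120
#>   EOD (female - male): +0.090
```

Female patients are flagged high-risk 12 percentage points more often
(DPD +0.120), and among truly readmitted patients, females are caught 9
points more often (EOD +0.090). Is that disparity distinguishable from
chance at this sample size?

```r
permutation_test_eod(test$outcome, predict(model, test, type = "class"),
                     test$gender, seed = substream_seed(42, "perm"))
#> Permutation test of |EOD| (N = 1000): observed 0.0900, p = 0.3756 ns
```

Not on this single split — which is exactly why the audit also reports
replicate and cross-validated behavior. Provenance shows the mechanism
for any individual decision:

```r
gender_flip_audit(model, test)
#> Counterfactual gender-flip audit (|p - 0.5| <= 0.15): 54 of 123 boundary cases flipped class (43.9%)

predict_with_provenance(model, test[1, ],
                        clock = afpr_clock("2026-01-01T00:00:00Z"))$provenance
#> Prediction provenance (logistic model c5c9bf77c4ce...)
#>   patient: P0002 at 2026-01-01T00:00:00Z
#>   probability 0.3695 -> class 0 (threshold 0.50)
#>   logit -0.5342 = intercept -0.6866 + contributions:
#>     age_std     bmi_std comorbidity      gender
#>      0.1302      0.0222      0.0000      0.0000
```

The one-call pipeline `run_full_audit(audit_config(seed = 42))` performs
all of the above for both model families, plus tuning, CV, ablation and
the sweep, and returns the validated AFPR document, a Markdown report
and CSV tables. A command-line front end with `simulate`, `audit`, `cv`,
`sweep`, `verify` and `report` subcommands is installed at
`inst/cli/fairaudit.R`.

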