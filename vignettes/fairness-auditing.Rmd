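---
title: "Provenance-based fairness auditing: models, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Provenance-based fairness auditing: models, conventions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fairaudit)
```

`fairaudit` studies a question that cannot be answered on real clinical
data alone: when a fairness audit flags (or clears) a risk model, is the
audit right? The package's answer is a controlled simulation in which the
bias is injected by construction, so every audit component — disparity
metrics, significance tests, counterfactual probes, provenance logs — can
be validated against a known ground truth before anyone trusts it in the
wild.

This vignette is the package's methodological record: the generating
model and its assumptions, every tunable that matters, the numerical
conventions, the design decisions that were genuinely open, and the
limits of what passing tests demonstrate.

## The synthetic cohort generator

Each of the `n_patients` (default 1000) patients carries:

* **age** (years): uniform on [20, 85]. The generating range is a stated
  assumption of the simulation; uniform is the simplest distribution
  consistent with it, and after z-scoring the exact shape matters little
  for the audit behavior studied here.
* **BMI** (kg/m²): Gaussian with mean 27, SD 5, clipped to [16, 45].
  Clipping happens *before* standardization, so the z-scores describe the
  clipped (realistic-support) variable.
* **comorbidity**: Bernoulli(0.35).
* **gender**: Bernoulli(0.5), coded 0 = female, 1 = male. This is the
  protected attribute throughout.

Age and BMI are z-scored over the full generated cohort *before* the
outcome is drawn, and all models are fit on the same standardized
columns. This makes the generating process self-consistent — the
coefficients below are per SD of the realized cohort — and avoids a
train/test standardization asymmetry. The alternative (re-standardizing
within training folds) changes third-decimal behavior only, but the
global convention is fixed here once.

The 30-day readmission outcome is a Bernoulli draw:

$$\Pr(Y=1 \mid x) = \sigma(-1.0 + 0.50\,\mathrm{age}_z + 0.40\,\mathrm{bmi}_z
 + 1.00\,C - 0.30\,G)$$

Stochastic labels (rather than deterministic thresholding of the linear
predictor) are the deliberate choice: they produce the moderate,
realistic accuracy regime in which fairness auditing is actually hard,
whereas thresholded labels would make the cohort separable and the audit
trivial. The default `beta_gender = -0.30` lowers male patients'
readmission odds by a factor e^0.30 ≈ 1.35 relative to otherwise
identical female patients — a clinically meaningful but not extreme
injected bias. With these defaults the outcome prevalence is ≈ 0.33 and
the Bayes-optimal accuracy of the generator itself is ≈ 0.71, which caps
what any fitted model can reach on this cohort.

**Seed discipline.** One master seed governs a run; every stochastic
stage (feature draws, outcome draws, splitting, CV folds, permutations,
per-grid-point sweeps) draws from `substream_seed(master, name, index)`,
a deterministic hash of the master seed and the stage name. Two
consequences worth knowing: the same features are generated regardless of
what happens downstream, and adding a stage (or a sweep grid point)
never perturbs the draws of existing ones.

## The audited models

`fit_logistic()` minimizes the summed negative log-likelihood plus
$\|w\|^2/(2C)$ on the feature weights (intercept unpenalized), with
C = 1, Newton iterations with step halving, a gradient tolerance of
1e-4 and at most 1000 iterations. The fit is deterministic;
non-convergence is a recorded warning, not a failure. At the cohort
sizes used here the penalty is numerically negligible (fits on 50,000
patients recover every generating coefficient within ±0.1) but it fixes
the convention exactly, and the test suite checks the fitted weights
against an independent numeric optimizer to 1e-6.

`fit_forest()` trains a probability forest: 100 trees by default,
bootstrap resampling, Gini-impurity splits, ⌈√p⌉ = 2 features tried per
split, unlimited depth (the sentinel 0 encodes "unlimited" in configs
and logs), minimum splittable node size 2. Each leaf predicts its class
proportion and the ensemble probability is the mean over trees — the
mean-of-leaf-proportions convention, chosen over majority-vote fractions
because it yields smoother probabilities at these sample sizes; a tree's
logged "vote" is its own probability thresholded at 0.5. Fitting is
backed by `ranger`; every tree's structure is extracted into the model
object, and all provenance replay (paths, votes, ensemble probability)
runs against those stored tables, so an archived model predicts
identically with no fitting backend present.

Classification uses threshold 0.5 with ties to the positive class,
uniformly everywhere.

`tune_forest()` evaluates the 18-candidate grid (trees {50, 100, 200} ×
depth {unlimited, 10, 20} × min split {2, 5}) by 3-fold
outcome-stratified CV on mean ROC-AUC, breaking ties by row-major grid
order for determinism.

## Fairness statistics and their conventions

All disparities are **female − male**, fixed once: positive DPD means
female patients are selected (flagged high-risk) more often; positive
EOD means truly readmitted female patients are detected more often. A
group with zero true positives has an *undefined* TPR — an explicit
error state, never a silent zero, because a 0 would masquerade as a
perfect-parity signal.

The permutation test holds predictions and outcomes fixed and permutes
the gender vector uniformly N = 1000 times, recomputing |EOD| each time;
p = (k + 1)/(N + 1). Permuted replicates in which a group draws no true
positives count as exceedances — the conservative resolution of an
ambiguity the procedure itself does not settle. Permutation is over the
whole test set (not within outcome strata), the plain reading of
"randomly permute the attribute". Significance bands are strict:
`***` p < 0.001, `**` p < 0.01, `*` p < 0.05, else `ns`.

Cross-validation is 5-fold, outcome-stratified, on the complete cohort;
fold summaries use t-based 95% intervals, mean ± t(0.975, df = k−1) ·
SD/√k, with the t quantile computed at runtime (2.776 for df = 4). Folds
whose held-out part lacks an outcome class, a gender group or a true
positive in either gender are flagged and excluded from the fairness
summaries with the degrees of freedom adjusted.

The counterfactual audit selects test cases with predicted probability
in the inclusive band [0.35, 0.65] and flips the gender bit of *every*
boundary case, in both directions, leaving all other features untouched
(gender is unstandardized, so no rescaling is involved). Both-direction
flipping is the deliberate reading: the flip's effect on a logistic
model is symmetric (|Δlogit| = |w_gender| either way), and restricting
to one direction would merely halve the sample without changing what is
measured. Double flips restore the original probability bit-exactly, and
for the logistic model a case flips iff the gender term carries its
logit across zero — both are tested properties.

The sensitivity sweep regenerates a fresh cohort per β value (all other
parameters fixed), refits and re-audits. The detection flag is
`EOD >= 0.05 AND learned coefficient < 0`: a deliberately
significance-free rule, because a subtle-but-real bias can move the
disparity without clearing p < 0.05 at n = 1000, and the sweep's purpose
is to characterize that behavior rather than hide it. The permutation p
is reported alongside.

## The AFPR document

The AI Fairness Provenance Record bundles (1) data provenance — the
generating spec, seed, feature semantics, demographic composition and
known limitations; (2) an ordered model-development log of configs,
metrics and rationale; (3) the append-only inference log; and (4) the
audit results. A JSON-Schema-style definition ships at
`inst/extdata/afpr-schema.json` and `afpr_validate()` reports violations
by JSON path.

Tamper evidence rests on two conventions chosen here because the
requirement ("hash-chained, canonical") does not fix them:

* **Canonical JSON**: object keys sorted bytewise, no insignificant
  whitespace, doubles rendered with the shortest decimal string that
  round-trips to the identical IEEE-754 value (negative zero normalizes
  to "0"; NA is unrepresentable by design). Logically equal documents
  hash identically regardless of construction order.
* **SHA-256 chaining**: each entry's hash is SHA-256 over the previous
  entry's hash concatenated with the canonical serialization of the
  entry body; the genesis previous-hash is 64 zero hex characters. The
  hash primitive is implemented in C++ (a few microseconds per entry;
  forest provenance entries carry 100 decision paths and are several
  kilobytes each) and is verified against published SHA-256 test
  vectors and independently computed digests.

Patient identifiers enter the inference log only as salted SHA-256
references; the salt is not part of the document. Timestamps come from
an injectable clock so that documents are reproducible under test.
Digital signatures, access control and storage engines are out of scope:
the package guarantees *detectability* of tampering given the document,
not *prevention*.

## Problem sizes and reproduction

The shipped study protocol is deliberately desk-scale: 1000-patient
cohorts, 70/30 splits, 5-fold CV, 1000 permutations, the 18-candidate
grid, and replicate means over 50 master seeds for every stochastic
summary (`scripts/acceptance.R`). A complete single-seed audit runs in
well under a minute; the 50-replicate protocol in a few minutes. The
calibration study (type-I error of the permutation test under
β_gender = 0 with a gender-blind model) uses 200 replicate audits, and
coefficient-recovery checks use one 50,000-patient cohort.

## What the simulation does and does not establish

Within its own world the suite verifies a closed loop: a known injected
bias is learned by both model families, surfaces in the fairness
metrics with the expected sign and ordering (larger and more often
significant for the linear model than for the ensemble), is traceable in
the provenance to the mechanism that carries it (a negative gender
weight; distributed low-importance tree usage), shrinks under the
gender-excluded ablation, and is detected across the sweep grid — while
under β_gender = 0 the permutation test's rejection rate stays at its
nominal level and the mean audited disparity vanishes.

The generator's features are mutually independent by construction, so
this cohort contains no proxy pathways: removing gender removes, in
expectation, *all* of the audited disparity. Real clinical data differ
in exactly the ways that matter most — correlated features that act as
proxies, missingness, measurement error, site and temporal effects,
multiple simultaneous biases. Passing this suite therefore demonstrates
that the audit machinery is correct and calibrated, not that it would
attribute disparities correctly in any particular real deployment. The
package's general-purpose entry points accept user cohorts with a binary
outcome and binary protected attribute, but conclusions drawn there
inherit all of those unmodeled complications.
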