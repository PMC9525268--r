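---
title: "Methods: windowed prediction of SLE hospitalization with Differential and LSTM models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed prediction of SLE hospitalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The prediction problem

Systemic lupus erythematosus (SLE) fluctuates between quiescence and
flares severe enough to require hospitalization. `slehorizon` treats
hospitalization risk as a family of supervised tasks indexed by an
observation window *X* (months of clinical history used as input; a
multiple of the 6-month binning interval, so the window spans
`k = X/6` steps) and a prediction horizon *Y* (months after the window
in which an event counts as positive). A patient whose regular series
has `b` usable bins contributes `b − k + 1` overlapping windows,
extracted step-wise one bin at a time; with the default six-bin
timeline that is `7 − k` windows per patient, so the dataset shrinks
by exactly one window per patient at each 6-month increase of *X*,
while totals are independent of *Y* because every window end retains a
full 12 months of follow-up. Labels use the half-open convention
`(end, end + Y]` so consecutive label intervals never double-count an
event, and an event exactly at a window's end belongs to that window's
horizon.

# Preprocessing

Clinical visits are irregular, so each patient's record is first
regularized onto 6-month bins (`[6b, 6(b+1))`, left-closed). Within a
bin, aggregation follows the feature's category: laboratory values are
averaged (multiple draws in a half-year act as one equivalent visit
and damp measurement noise), binary manifestation/medication flags
take the maximum (observed at any visit ⇒ present in the half-year),
and utilization counts are summed (utilization is additive). Only labs
are averaged; the max/sum rules for the other categories are this
package's choice, made on the clinical reading just given.

Missing cells are then filled per feature from that patient's own
observed bins: interior gaps by pass-through piecewise-linear
interpolation (observed values are reproduced exactly), leading and
trailing gaps by extrapolating the least-squares line through the
observed points, and a single observed point is held constant.
"Linear interpolation/extrapolation fitted to the observed points" is
ambiguous between pass-through and a single fitted line; we use
pass-through inside the observed range because it preserves data, and
the least-squares line outside because extrapolating the segment
through a noisy first or last point is fragile. `lsEverywhere = TRUE`
switches to the single fitted line throughout. Binary features are
clipped to [0, 1] and counts floored at 0 after imputation; observed
cells are never altered, which makes imputation idempotent. A feature
a patient never has observed falls back to the cohort mean with a
warning. Whether binning should precede imputation is itself a design
choice; the default bins first (the imputation grid is then the
modelling grid), and `order = "impute_first"` fills visit-level cells
before binning instead.

# The two models

**Differential.** Each window becomes one row: 5 demographics, the 52
clinical features at each of the `k` steps, and 52 lagged change
variables `Δx_t = x_t − x_{t−1}` for each consecutive step pair
(`p = 5 + 52k + 52(k−1)` columns; for `k = 1` there are no deltas).
Keeping all raw steps alongside the deltas is deliberate — it supersets
the alternative of first-step-plus-deltas, which remains available as
`layout = "compact"`. The deltas are linearly redundant given all raw
steps, but they present disease *change* explicitly to learners (trees,
naive Bayes) that do not form linear combinations themselves. The
classifier is a soft-voting ensemble of six non-temporal learners —
decision tree, random forest, ridge-penalized logistic regression,
Gaussian naive Bayes, one-hidden-layer neural network, RBF-kernel SVM
with probability outputs — averaged first over learners within a bag,
then over balanced bags. Soft voting (mean class-1 probability) is the
default because AUC needs a continuous score; `voting = "hard"` counts
votes instead. Scale-sensitive learners (logistic, network, SVM)
receive standardized features, with the scaler fit on training rows
only; trees, forests and naive Bayes see the raw panel. Standardization
of a column is skipped when its training values all lie in {0, 1}
(binary), and a zero-variance column is centered with scale 1.

**LSTM.** The same windows as `n × k × 57` sequences (52 clinical per
step + the 5 demographics repeated at every step, making sequences
equal-length without lagged variables). The cell follows the standard
gate equations on `z = [h_{t−1}, x_t]`; the read-out is an affine map
of the last hidden state through a logistic — the read-out form is not
fully pinned down by the architecture sketch we follow, and
affine+logistic is the conventional completion. Weights initialize
uniformly in ±1/√(h+d) with forget-gate bias 1; training is mini-batch
Adam (defaults: 50 epochs, batch 72, learning rate 1e-4) on binary
cross-entropy, implemented with exact backpropagation through time
(verified against finite differences in the test suite to 1e-5).

**Imbalance.** Positives are 1–7 % of windows. The Differential model
uses bagging with random undersampling: each bag = all minority
windows + an equal number of majority windows drawn with replacement
from the whole majority pool, so every bag is exactly 50/50; the
number of bags (default 100) is a hyperparameter. The LSTM instead
duplicates each minority sequence `r − 1` times, `r` the
majority/minority ratio rounded half-to-even (`rounding = "floor"`
truncates); duplication is deterministic. Both schemes are applied to
training data only — never to evaluation folds — and the
cross-validation code records, per fold, every index that entered a
bag, an oversample multiset or a scaler fit, so the no-leakage
property is machine-checkable.

# Evaluation

`nestedCV()` follows the classical two-level scheme: outer folds
(default 20) estimate generalization as the arithmetic mean of per-fold
metrics (no pooling); within each outer training set, inner folds
(default 20, reducible to 5 for desk-scale runs) score each candidate
hyperparameter setting by mean AUC and the winner is refit once on the
full outer-training data. Folds are stratified by default — at 1–2 %
prevalence an unstratified 20-fold split frequently yields
positive-free folds with undefined recall/AUC — and assignment keeps
both fold sizes and per-fold positive counts within one. The default
candidate list is the single default setting; `defaultEnsembleGrid()`
supplies the small per-family grids (tree depth {3, 5, 10}; forest
node limit {32, none}; ridge penalty {0.1, 1, 10}; network size
{16, 64}; SVM cost {0.1, 1, 10}; LSTM hidden size {16, 32, 64}) from
which users can assemble candidates; exhaustive products are
deliberately not the default because nested CV multiplies their cost
by `outer × inner` fits.

Metrics come from the confusion matrix at score threshold 0.5 plus the
rank-based (Mann–Whitney) AUC with ties counted ½, verified in the
tests against the brute-force pairwise statistic. The "F0" slot of the
metric set is Fβ with configurable β, default 0.5: Fβ at β = 0
degenerates to precision exactly, duplicating PPV, so a
precision-weighted β is the useful reading. Undefined ratios (PPV with
no positive predictions; AUC with one class) are reported `NA`, never
coerced to 0. `runGrid()` runs the full X × Y × model factorial and
`reportGrid()` renders per-metric tables with Differential (D), LSTM
(L) and L−D columns.

**Instance-level vs patient-grouped splitting.** Overlapping windows
of one patient are kept as separate instances, and instance-level
splitting is the default to mirror the original protocol. But whenever
`Y` exceeds the 6-month step, the label intervals of consecutive
windows of a patient overlap, so an instance-level split lets held-out
windows share label information with training windows of the same
patient; empirically this biases even a null model's AUC above chance.
All calibration checks in this package therefore evaluate with
`groupByPatient = TRUE`, which assigns whole patients to folds; the
toggle is available everywhere.

# The synthetic cohort generator

The generator emulates the *structure* reported for the motivating
cohort: 925 patients, 5 static demographics, 52 time-stamped features
in four categories (14 manifestations, 12 medications, 16 labs, 10
utilization), irregular visits (Poisson, mean 2 per 6-month bin,
uniform times), per-feature per-visit missingness (default 0.15), six
observation bins plus 12 months follow-up, and binary hospitalization
outcomes whose prevalence grows with the horizon (roughly 1.5 % at
Y = 3M to 6–7 % at Y = 12M under the defaults, matching the 1.3–6.45 %
range of the study design it emulates).

Each patient carries a latent monthly disease activity
`a(m) = μ_i + s_i·m/6 + u(m)`: a patient intercept
(`interceptSd = 0.8`), a patient-specific linear drift per 6 months
(`driftSd = 0.35`) and an AR(1) deviation (`arPhi = 0.8`,
`arSd = 0.15`). The drift term matters: under a pure AR(1), 6-month
*changes* are serially almost uncorrelated, so a hazard driven by
recent change would be unpredictable from window-observed deltas and
the Differential premise could never be validated. With the drift,
recent change persists across the window/horizon boundary and lagged
difference features carry real, recoverable signal. Observed features
are noisy functions of activity — labs linear-Gaussian
(`labNoiseSd = 0.6`), flags thresholded Gaussians, utilization
Poisson with log-linear rate — and events are drawn month-by-month
with hazard `logistic(hazardBase + betaLevel·a(m) +
betaDelta·[a(m) − a(m−6)])`, defaults `−7.5 + 0.8·level + 2.5·change`
(the change effect dominant, `signalPreset()`). `nullPreset()` sets
both effects to 0 with `hazardBase = −5.27`, giving the same ~6 %
12-month prevalence with outcomes independent of all features; the
12-month event probability then has the closed form
`1 − (1 − plogis(hazardBase))^12`, which the tests check empirically.
The baseline hazard was calibrated once, while designing the
generator, to put prevalence in the emulated range, and is not
adjusted thereafter.

What the generator does **not** emulate: real marginal distributions
of the 52 features (only the category types are meaningful),
informative visit frequency (sicker patients visiting more often),
multi-site heterogeneity, label misclassification from
out-of-system hospitalizations, or any real SLE pathophysiology. One
visible artefact of the drift term is that later windows carry higher
event prevalence, so prevalence grows mildly with *X* under the
defaults, whereas the emulated study reports it roughly flat-to-
decreasing in *X*. Passing tests on this cohort therefore demonstrate
that the pipeline's mechanics are correct and that each model recovers
the kind of signal it claims to capture — not that any particular
performance level would transfer to real records.

# Numerical and scale choices

Deterministic behaviour: every stochastic step (generation, bags,
folds, learner fitting, LSTM initialization and batch order) takes an
explicit seed and restores the caller's RNG state. Standardization
uses R's sample standard deviation. The oversampling ratio rounds half
to even. Tie-breaks in hyperparameter selection take the first
maximum. The LSTM clamps probabilities to [1e-12, 1−1e-12] inside the
loss and aborts on a non-finite loss rather than continuing.

Problem sizes in the shipped checks were chosen to keep the default
test run at desk scale: unit tests use 25–120-patient cohorts and
2–20-bag ensembles; the end-to-end calibration checks use the
full-size 925-patient cohort with 20 bags and a single stratified
patient-grouped 75/25 split (the count-identity checks are exact at
any scale and use the full grid). The acceptance script follows the
same pattern and trains the LSTM with the full study regime (50
epochs, batch 72, lr 1e-4).

# Known limitations

- The six base learners follow their R implementations (`rpart`,
  `randomForest`, `glmnet`, `e1071`, `nnet`); hyperparameter grids are
  small by design and not exhaustive reproductions of any particular
  search space.
- SVM probability outputs use Platt scaling with internal CV, which
  consumes RNG draws; bagged scores involving the SVM are reproducible
  under a fixed seed but not invariant to bag reordering.
- The LSTM is a single-layer implementation in base R; it is exact and
  fully tested but not performance-tuned for very long sequences
  (windows here have at most 6 steps).
- `"F0"`-style reporting uses β = 0.5 by default; any β > 0 is
  supported, β = 0 is precision by definition.
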