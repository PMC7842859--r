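---
title: "Federated learning on simulated multi-hospital cohorts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Federated learning on simulated multi-hospital cohorts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fedcohort)
```

## The problem

Clinical prediction models need large, diverse training sets, but hospital
records are siloed: privacy regulation usually forbids pooling raw
patient-level data across institutions. Federated learning sidesteps the
problem by exchanging only model parameters with a central aggregator.
`fedcohort` studies this trade-off for 7-day in-hospital mortality
prediction across five hospitals of very different size (485 to 1644
admissions) and outcome prevalence (5.6% to 24.2%), comparing three
training strategies under one evaluation protocol:

* **local** — each hospital trains on its own data only;
* **pooled** — one model on the concatenated data of all hospitals, the
  idealized upper reference that full data sharing would permit;
* **federated** — parameters move, data never does.

Because the underlying hospital records are private, the package ships a
synthetic cohort generator calibrated to the published site profiles, so
every experiment in this vignette and in the test suite is fully
reproducible from a single seed.

## The cohort generator

Each site is described by a `site_profile()`: patient count, 7-day
mortality prevalence, gender split, age median/IQR, probability vectors
for ethnicity and race, nineteen comorbidity-flag prevalences, and
(mean, sd) pairs for eight admission vitals and labs.
`default_mshs_profiles()` carries the published five-site description;
categorical probabilities are built from the published counts, so they sum
to one exactly.

Features are drawn independently within a site: binary flags are
Bernoulli, categoricals multinomial, continuous features Normal. Age uses
a Normal fitted to the printed median and IQR (sd = IQR/1.349, the normal
IQR-to-sd factor) truncated to [18, 110] years — the simplest model
consistent with the printed summaries. Cells the published table masks for
privacy (fewer than 10 patients) have no printed prevalence; they default
to 0.01, consistent with the masking threshold, and are overridable.

The outcome mechanism is the one deliberate invention in the generator:
the true data-generating process of the source system is unknowable, so
outcomes follow a logistic linear model whose coefficient vector is
**shared across sites** (default: five nonzero coefficients — age, SpO2,
CRP, heart failure, diabetes — out of 35 encoded columns), with a
**per-site intercept** solved by bisection so each site's expected
mortality equals its configured prevalence to within 1e-6. Sharing the
coefficients gives cross-site learning a recoverable signal, which is the
premise that makes federation worth studying; the calibrated intercepts
reproduce the real prevalence spread. Sparsity makes coefficient-sign
recovery by L1 training a testable property.

Two further realism knobs:

* **site shift** (`shift_sd`, default 0.25): continuous feature means are
  offset per site by `shift_sd * sd * z_i` with `z_i` evenly spaced in
  [-1, 1], emulating the significant cross-site differences the source
  system reports for most clinical features;
* **missingness** (`missing_rate`, default 0): optional
  missing-completely-at-random cell deletion for robustness testing; the
  reference pipeline assumes complete data.

What the generator does **not** emulate: correlated comorbidity structure,
longitudinal vitals, coding drift between hospitals, informative
missingness, or any real covariate-outcome relationship. Passing tests
therefore demonstrate correctness of the machinery and qualitative
behavior under a known shared-signal regime, not real-data performance;
the published real-data AUROCs are shipped only as a qualitative benchmark
(`reference_auroc()`).

## Interhospital comparison tables

`build_comparison_table()` reproduces the standard "Table 1" machinery:
counts and percentages (one decimal) for binary/categorical
characteristics, median and IQR for numeric ones, uncorrected Pearson
chi-square across sites for categoricals, Kruskal-Wallis for numerics, and
masking of cells describing fewer than 10 patients. Two choices deserve
explanation:

* **No continuity correction.** On the published five-site contingency
  tables the uncorrected Pearson statistic reproduces the printed
  p-values (gender .004, atrial fibrillation .005, heart failure .38,
  COPD .04) exactly at their printed precision; Yates correction does not.
* **Bonferroni scope.** The published footnote reports
  Bonferroni-adjusted p-values but the printed categorical p-values match
  unadjusted chi-square, so by default adjustment is applied to the
  numeric (Kruskal-Wallis) tests only, with `m` equal to the number of
  tests in scope. The scope is configurable (`adjust = "all"` or
  `"none"`); the default follows the printed evidence without claiming to
  know the original intent.

## Models and training

Both classifier families share one parameter container (ordered
weight/bias layers plus an architecture tag) so that the federation layer
can average either of them:

* **LASSO** — a single sigmoid layer trained by gradient descent with a
  proximal soft-threshold of magnitude `learning_rate * l1_lambda` applied
  to the weights (never the bias) after every update. This is an
  iterative, parameter-space realization of L1-regularized logistic
  regression rather than a coordinate-descent solver, because federation
  averages *parameters* each round and therefore needs an iterative
  parameter-space trainer. Exact zeros still occur (the soft-threshold is
  exact), so the usual sparsity-path behavior is preserved.
* **MLP** — a feed-forward network with rectifier hidden layers (default:
  one hidden layer of 32 units) and a single sigmoid output. The
  architecture is held identical across strategies within an experiment so
  that strategy comparisons are not confounded by capacity.

Training minimizes the (optionally sample-weighted) mean binary
cross-entropy by backpropagation. Defaults — Adam, learning rate 1e-3,
mini-batches of 32, `l1_lambda` 1e-3 — are modest-capacity choices
appropriate to roughly 40 features and at most a few thousand rows per
site; the original study's exact hyperparameters are not public, and every
value is overridable in the experiment config. Initialization is
Glorot-uniform with zero biases, deterministic per seed. Scores are
clipped to [1e-12, 1-1e-12] inside the loss only; gradients use the exact
sigmoid output. A non-finite loss or parameter aborts training with an
error naming the site and round, rather than silently producing garbage.

## Federation

`run_federated()` simulates the aggregator protocol: initialize global
parameters from the federation seed; each round, send them to every site,
train `local_epochs` epochs (default 1) on that site's data only, then
replace the global model with the **sample-count-weighted mean** of the
site parameters, layer by layer. Three design points:

* **Optimizer state stays local.** Only weights and biases are exchanged;
  Adam moments are re-zeroed at each site every round, because the
  protocol exchanges model parameters only.
* **Noise before transmission.** With `noise_sigma > 0` each site adds
  independent Normal(0, sigma^2) noise to every outgoing entry — the site,
  not the aggregator, perturbs, matching the privacy motivation. Sigma is
  an absolute per-entry standard deviation, default 0 (the headline
  configuration), because an absolute scale is auditable.
* **Weights are the rows actually trained on.** The averaging weight
  `n_k` is the site's post-balancing training-row count, on the reading
  that "available data points" means the data the update was computed
  from.

The load-bearing correctness argument is an exact identity: with
full-batch plain gradient descent, one local epoch per round and no noise,
the pooled mean-loss gradient is the n-weighted mean of the site
gradients, so R federation rounds coincide with R pooled descent steps to
floating-point accuracy. The test suite and the acceptance script verify
this to relative 1e-8 (observed ~1e-15) for both families on a 3-site
system (n = 60/40/20, d = 8, R = 20); it is the module's primary oracle.
Data isolation is structural: the site trainer receives only its own
matrix, so no code path can leak rows between sites.

Round budgets default to 50 for LASSO and 30 for the MLP — enough for the
learning curves to flatten at the default learning rate — and local and
pooled runs get the same number of epochs so every strategy makes the same
number of passes over the data. Early stopping is deliberately absent:
fixed-epoch curves are the reported output.

## Preprocessing and evaluation protocol

Encoding is deterministic in schema order (binary as 0/1, one-hot with the
first level as dropped reference, continuous as-is), so two cohorts under
one schema always produce identical column sets — the property that makes
locally encoded matrices federable.

The evaluation protocol is B independent stratified 70/30 train/test
resplits (Monte-Carlo cross-validation), one fresh split per iteration
with seed `master_seed + iteration`. The reference protocol uses B = 490;
the package's desk default is B = 50, which keeps a full two-family
federated-versus-local comparison within minutes on one core while leaving
the Monte-Carlo error of a mean AUROC around a few thousandths. Within
each iteration and site:

1. stratified split (test positives = `round(0.3 * n_pos)`);
2. standardization of continuous columns fitted on the training part only;
3. class balancing of the training part only (default: oversample the
   minority to parity; undersampling, inverse-frequency weights, or none
   are available). Balancing after splitting, and scaling per training
   fold, are leakage hygiene — the original ordering is not stated, so the
   defaults err on the conservative side.

Every trained model is scored on every site's test part with the
rank-based (Mann-Whitney) AUROC with midrank ties; the per-site summary
for the local strategy is the diagonal (each site's own model), while the
full train-site-by-test-site matrix is retained. Per-site AUROC vectors
are summarized by mean and percentile 95% interval (type-7 linear
interpolation) — assumption-light, with a normal-approximation interval
available by flag. A test part that loses one class (possible at 5.6%
prevalence) triggers a deterministic re-split (seed offset 100000 per
attempt), never a silent drop, so B stays fixed and reproducible; such
events are logged in the result object.

## Numerical choices and degenerate inputs

* Bisection for site intercepts runs on [-20, 20] in log-odds, tolerance
  1e-6 on the mean risk; targets of exactly 0 or 1 are rejected as
  unattainable with finite logits.
* Constant columns are never scaled (sd guard at 1e-12); 0/1 columns are
  detected as indicators and left untouched.
* All-tied Kruskal-Wallis input (every pooled value identical) returns
  statistic 0 and p = 1 instead of the 0/0 tie correction.
* Chi-square requires strictly positive marginals; empty rows or columns
  are an error rather than an NaN.
* Every random draw goes through an internal helper that sets the seed and
  restores the caller's RNG state, so package calls never perturb a user's
  random stream; per-site, per-iteration and per-round seeds are fixed
  small offsets of the master seed.

## Worked scales used by the shipped checks

The packaged tests and `scripts/acceptance.R` run on deliberately modest
problem sizes chosen to exercise every property at comfortable desk cost:
the full five-site synthetic system (4029 patients, 35 encoded columns)
for generation, comparison tables, sign recovery and the B = 50
federated-versus-local contrast at the MSW analog; a 3-site system
(n = 60/40/20, d = 8) for the federation/pooling identity; and
10,000-entry parameter vectors for the noise contract. At these scales the
qualitative published pattern replicates: the federated model beats the
local model at the smallest, most imbalanced site for both families, while
pooling remains the upper reference. The package reports no empirical
claim beyond what those scripts compute.

## Known limitations

* Feature independence within site is unrealistic; real comorbidities and
  labs are strongly correlated. Effect sizes of federation on real data
  cannot be inferred from this simulation.
* The published per-site AUROCs are not reproducible here by construction
  (private data); they are shipped for qualitative comparison only.
* The exact feature panel, balancing methods and model hyperparameters of
  the source study are unpublished; the package documents its stand-ins
  and makes each overridable.
* No secure aggregation, differential-privacy accounting, stragglers or
  transport failures: the aggregator is simulated in-process. The Gaussian
  noise option is a mechanism study, not a formal privacy guarantee.
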