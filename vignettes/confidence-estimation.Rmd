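---
title: "Confidence estimation for regression predictions: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Confidence estimation for regression predictions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regconf)
```

## The problem

Regression models in computational life science — QSAR activity models,
MHC–peptide binding predictors and the like — usually emit a bare number.
Global accuracy statistics (a test-set correlation, an RMSE) say nothing
about how trustworthy *one particular* prediction is: a query deep inside a
well-populated region of descriptor space is a very different proposition
from one at the edge of the training data. This package attaches to every
prediction a normalized confidence score and an empirical confidence
interval, using only the training data and (optionally) the model — no
distributional assumptions, and no access to the model's internals.

## Raw confidence scores

A confidence estimator maps a query $x$ (plus training data $T$, and for
some estimators the model $f$) to a raw score where **larger means more
confident**. Eight estimators are implemented; all scores are negated
errors/variances/distances so the sign convention is uniform:

* **CONFINE** (neighbors' errors): $-\frac{1}{k}\sum_{i \in N_k(x)} e_i^2$,
  where $e_i$ are out-of-fold training errors and $N_k(x)$ the $k$ nearest
  training rows by Euclidean distance. The local error of the model is
  transferred to the query. A kernel variant replaces the hard
  neighborhood with Gaussian weights $w_i = \exp(-d_i^2 / 2h^2)$.
* **CONFIVE** (variance in the environment): negated sample variance of
  the $k$ nearest neighbors' *response values*. Model-independent: a
  locally heterogeneous response is hard for any regressor.
* **NoNN**: the number of training rows within a radius (a density
  estimate of the applicability domain).
* **Diff5NN**: $-|\hat y - \bar y_{N_5(x)}|$, the disagreement between the
  prediction and the 5-neighbor response mean.
* **AvgDist**: negated mean distance to all training rows.
* **LocalCV**: distance-weighted mean of leave-one-out absolute errors of
  the $k$ nearest neighbors (each neighbor predicted by a model refitted
  without it).
* **LocalVar**: the query is injected into the training set with
  perturbed response values; the model is refitted per perturbation and
  the variance of the re-predictions is negated (local sensitivity).
* **Bagging**: negated variance of predictions from bootstrap-resampled
  models (default $B = 20$).

Raw scores are not comparable across estimators. They are normalized
against the training distribution: the **normalized confidence score**
(ncs) of a query is the fraction of training instances with a *strictly*
smaller raw score — an empirical-CDF rank in $[0, 1]$. Training instances
are scored with self-exclusion (a row is never its own neighbor), so the
training ncs values form a near-uniform grid.

## From scores to intervals

Instances with similar ncs are assumed to have similar errors. The
calibration table stores, per training instance, its self-excluded raw
score, ncs, and signed out-of-fold error $y_i - \hat y_i$. For a query
with score $s$, the error pool is the set of training entries with
$|\mathrm{ncs}_i - s| \le w$ (window half-width $w = 0.1$ by default); if
fewer than `min_pool` (default 30, or $n$ if smaller) qualify, the pool is
expanded to the `min_pool` nearest-ncs entries. The interval at level
$1-\alpha$ is

$$[\hat y + Q_{\alpha/2}(\mathcal E),\; \hat y + Q_{1-\alpha/2}(\mathcal E)]$$

with $Q_p$ the *nearest-rank* empirical quantile (the $\lceil p\,m\rceil$-th
smallest value, no interpolation) of the pooled **signed** errors. Signed
errors make the interval absorb local bias — it may sit asymmetrically
around the prediction. A *general* interval uses all training errors
regardless of score; it has the same width everywhere and serves as the
uninformed reference.

Numerical choices worth stating: nearest-rank quantiles are used for
bit-exact testability and assumption-freeness; pooling windows are closed
($\le$, with a $10^{-12}$ guard against representation error); ncs ties
count strictly below, so tied raw scores deflate a score rather than
inflate it; neighbor ties are broken by ascending row index so every run
is reproducible.

## Evaluation metrics

* **CEC** (confidence–error correlation): Pearson correlation between
  absolute test errors and interval widths, normalized by the correlation
  obtained after sorting both vectors — the best any estimator could do
  given the two marginal distributions. CEC is 0 for an uninformative
  estimator and 1 for a perfect ordering; if either vector is constant
  the value is defined as 0 and flagged degenerate so batch runs never
  abort.
* **CAPI** (confidence-associated prediction improvement):
  $1 - \mathrm{MSE}(\text{top fraction})/\mathrm{MSE}(\text{all})$ where
  the top fraction (default 50%) are the predictions with the smallest
  intervals.
* **Coverage**: the fraction of true responses inside the closed interval;
  for a calibrated 80% interval this should approach 0.80.
* **CEC predictability**: the correlation between CECs measured on
  training data and on the corresponding test data, one pair per
  dataset/fold.

## The evaluation protocol

`nested_cv_evaluate()` repeats an outer 5-fold cross-validation five
times. Inside each outer-training part it (1) selects features greedily
by 5-fold CV MSE (stopping when no addition improves the MSE by at least
1e-6 relative), (2) standardizes features by training mean and sample SD
— unscaled Euclidean distances would be dominated by whichever descriptor
has the largest units — (3) fits the model, (4) computes out-of-fold
training errors (5-fold CV rather than resubstitution: the less
optimistic reading), (5) tunes $k$ where requested, and (6) builds the
calibration table. Only then is the outer-test part scored. Outer-test
rows never enter any training-side artifact; the test suite verifies this
with a canary that permutes the held-out responses.

$k$ is tuned by five two-fold cross-validations: per half-split the
estimator is calibrated on one half and evaluated (CEC of the resulting
intervals) on the other; the per-fold argmax over a geometric candidate
grid $\{2, 4, 8, 16, 32, 64\}$ (clamped to the half size) is recorded and
the rounded mean of the ten argmaxes returned. Two-fold splits keep the
held half large, which the CEC needs; the geometric grid covers the
useful range at logarithmic resolution — CEC responds smoothly to $k$, so
finer steps buy little at substantial cost.

## Synthetic data

`generate_friedman()` draws `m_total` features uniformly on $[0,1]$ and
computes $y = 10\sin(\pi x_1 x_2) + 20(x_3 - 0.5)^2 + 10 x_4 + 5 x_5 +
\varepsilon$, $\varepsilon \sim N(0, \sigma^2)$. Two terms are linear, two
nonlinear; features beyond the fifth are pure nuisance. The generator
emulates a controllable benchmark: dataset size, dimensionality and noise
can be swept independently, which is exactly what the grid study does
(`default_grid()`: $n \in \{50, 100, 200, 500\}$, $m_{total} \in
\{5, 10, 25, 50\}$, $\sigma \in \{0.5, 1, 2\}$, 3 replicates). What it
does *not* emulate: correlated descriptors, discrete/one-hot geometry,
heteroscedastic or heavy-tailed noise, and covariate shift between
training and test data — all present in real QSAR/MHC data. Passing the
synthetic suite therefore demonstrates correctness of the machinery and
the qualitative behavior of the estimators, not performance on any
particular real dataset.

For the sequence path, `encode_peptides()` maps 9-mers to $9 \times (20 +
6) = 234$ features: a one-hot block in fixed alphabetical order plus six
physicochemical values per position (Kyte–Doolittle hydrophobicity,
Hopp–Woods hydrophilicity, net charge at pH 7, Eisenberg consensus
hydrophobicity, polarity and aromaticity flags). The six-column property
table is a bundled stand-in assembled from standard published scales and
can be overridden with any 20×6 matrix.

## Design decisions on genuinely open points

* **Error mode.** Training errors for CONFINE default to 5-fold CV;
  resubstitution is selectable. CV errors are systematically larger on
  noisy data (a tested property) and avoid transferring optimism into
  the confidence score.
* **Distance standardization.** All neighbor searches run on z-scored
  features using training statistics; zero-variance columns map to zero.
* **LocalCV scope and k.** The leave-one-out refits use the full training
  set minus one neighbor by default (`localcv_scope = "full"`), with a
  neighborhood-only variant behind a flag, and $k$ defaults to 10. This
  configuration makes LocalCV carry nearly the same signal as CONFINE
  with absolute errors: on large low-noise Friedman data the two are
  statistically indistinguishable, whereas a runtime-minimal $k = 2$
  (LocalCV is typically run with a strongly reduced $k$ because each
  estimate costs $k$ model refits) makes it markedly weaker than CONFINE.
  Users who want the classical weak-but-cheap behavior should set a small
  $k$; the default favors estimation quality.
* **LocalVar perturbations.** Fractions $\{\pm 0.5, \pm 0.1, \pm 0.01\}$
  of the training response range, symmetric about zero; configurable.
* **NoNN radius.** Defaults to the median distance to the 5th nearest
  neighbor among training rows — a density-adaptive choice; configurable.
* **Kernel bandwidth.** Defaults to the median pairwise training
  distance.
* **CAPI top fraction.** 50%; a config key, since the reference value is
  not fixed by the method.
* **Degenerate cases.** Constant widths or errors give CEC/CAPI 0 with a
  degenerate flag rather than an error; a constant training response is
  an error for LocalVar (its perturbation scale is the response range);
  kernel weights that all underflow raise a degenerate-neighborhood
  error rather than returning 0/0.

## Problem sizes used in the shipped studies

The packaged grid study runs the full default grid (144 cells) with five
repeated 5-fold nested cross-validations per cell and four estimators
(CONFINE, CONFIVE, bagging, Diff5NN) under OLS — about 8–10 minutes on
one CPU. The estimator-ordering studies use 20 seeds of single-repetition
nested CV at $n = 500$ (and the size comparison aggregates $n \in \{50,
100\}$ vs $\{200, 500\}$ across $\sigma \in \{0.5, 2\}$); the coverage
study uses one 1600/400 train/test split. These sizes were chosen so the
statistical claims are testable at desk scale while each check still has
enough folds to average over.

## Known limitations

* CEC on a single fold of 10–100 test points is noisy; conclusions should
  be drawn from averages over folds and conditions, which is how the
  harness reports them.
* With many nuisance features and small $n$, the greedy selection admits
  noise features (about 10 of 50 at $m_{total} = 50$), which degrades all
  neighborhood-based estimators; this mirrors the behavior the method is
  designed to expose, but means bin averages over high-dimensional cells
  sit well below the clean-cell values.
* Bootstrap-ensemble (bagging) confidence tracks leverage; on data where
  large-sample error is bias-dominated its advantage at large $n$ may not
  materialize.
* The OLS and RBF-SVR families are bundled; any other model can be used
  by extending `fit_predictor()`/`predict()`, but SVR hyperparameters are
  not auto-tuned per fold.

## A minimal worked example

```{r example, eval = FALSE}
train <- generate_friedman(400, m_total = 10, sigma = 1, seed = 1)
query <- generate_friedman(5, m_total = 10, sigma = 1, seed = 2)

cr <- conf_regressor(train, predictor_spec("ols_linear"),
                     estimator_spec("confine"), alpha = 0.2, seed = 3)
predict(cr, query)
```

The result has one row per query: the prediction, its raw and normalized
confidence scores, and the 80% interval bounds. High-ncs rows carry
visibly narrower intervals; that width ordering, not the absolute score,
is what the CEC and CAPI metrics quantify.
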