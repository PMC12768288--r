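---
title: "Methods: CARS feature selection, Kepler-optimised tuning and stacking for multimodal seed classification"
author: "koastack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CARS, KOA tuning and stacking for multimodal seed classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Crop seed varieties of the same species are often morphologically nearly
indistinguishable, yet cultivar identity drives yield and nutritional
profile. `koastack` implements a non-destructive classification pipeline
that fuses two complementary measurement modalities of individual seeds:

* **Raman spectra** — inelastic-scattering intensities on a fixed Raman-shift
  axis, here 400–1800 cm⁻¹ sampled every 2 cm⁻¹ (700 channels), which probe
  the seed's biochemical composition; and
* **image-derived numeric features** — 43 descriptors per seed (18
  geometric, 7 texture, 18 colour in RGB/HSV/LAB), which capture external
  morphology.

The reference experimental design the package targets is a panel of 7
varieties × 100 seeds (700 samples), split 4:1 into training and test sets.

## Pipeline overview

1. **Preprocessing.** Spectra are smoothed with a Savitzky–Golay filter
   (window 15 channels, polynomial order 3) via `signal::sgolayfilt()`;
   both modalities are then min–max scaled, `(x − min)/(max − min)`.
2. **Feature selection.** Competitive adaptive reweighted sampling (CARS)
   is run independently per modality.
3. **Early fusion.** The selected spectral block (first) and image block
   are concatenated column-wise, with provenance retained per column.
4. **Hyperparameter tuning.** The Kepler optimization algorithm (KOA)
   tunes six classifier families — DT, SVM, KNN, MLP, RF, GBDT — by
   minimising a cross-validated misclassification rate.
5. **Stacking.** The tuned models become base learners of a two-layer
   stacking ensemble; out-of-fold predictions form the meta-features, and
   the meta-learner is chosen combinatorially among the same six families.
6. **Evaluation.** Accuracy, one-vs-rest precision/recall/F1 (macro
   averaged), confusion matrices and one-vs-rest ROC AUC on the held-out
   test split.

```{r}
library(koastack)
cfg <- run_config(koa = koa_config(pop_size = 10, max_iter = 20), seed = 1)
res <- run_pipeline(cfg)
res$evaluation$accuracy
```

## CARS

CARS treats variable selection as iterated competitive survival. With `m`
features and `N` sampling runs, run `i` retains the fraction

r_i = a · exp(−k·i),  a = (m/2)^(1/(N−1)),  k = ln(m/2)/(N−1),

so r_1 = 1 (all features) and r_N = 2/m (two features) exactly — the
*exponential degradation function* (EDF). Each run fits a PLS regression on
a Monte-Carlo row subsample of the surviving features, keeps the
`round(r_i·m)` features with the largest absolute regression coefficients
(competitive elimination), then applies *adaptive reweighted sampling*:
`n` draws with replacement, probability proportional to weight, retaining
the unique drawn features. The survivors are scored by RMSECV (pooled
root-mean-square error of a k-fold cross-validated PLS fit on the full
data), and the subset with the lowest RMSECV over all runs is selected,
taking the earliest run on ties (a deterministic, simple rule).

Configuration defaults (classic CARS practice): 10 PLS components (capped
by rank), 5 CV folds, 80% Monte-Carlo row sampling, `N = 20` runs.
Class labels enter the PLS regression as integer codes 1..C by default —
the classic chemometric shortcut, consistent with RMSECV magnitudes around
1.5 on a 7-class problem — with one-hot encoding available
(`pls_config(label_encoding = "one-hot")`).

The PLS engine is an internal SIMPLS implementation: CARS calls PLS inside
a tight resampling loop and needs only centred fits and raw coefficients.
The test suite verifies it against an independent PLS implementation
(mixOmics) to numerical precision on univariate-response fits.

## KOA

KOA is a population metaheuristic: candidate solutions are planets, the
incumbent best is the Sun. Two published update rules drive the search.

*Orbital update* — X′ = X + F·V + (Fg + |r|)·U·(X_S − X): a partial,
randomly masked contraction toward the Sun plus a velocity term.

*Distance-adaptive update* — with M = (X + X_S + X_a)/3,
X′ = X·U1 + (1−U1)·M + (1−U1)·h·(M − X_b): a move toward a population
mean, inflated away from a random planet by the regulating parameter `h`
(large `h`: exploration; small: exploitation).

Everything that generates the inputs of those rules is mechanics the
package had to choose; each constant is a `koa_config()` field so the
mechanics are auditable and overridable:

* planet masses from normalised fitness, Sun mass 1;
* gravity `Fg = ecc · mu0 · exp(−gamma_mu·t/T) · mass/(R² + ε)` with `R`
  the Sun-distance normalised by the population maximum, capped at
  `fg_cap`;
* velocity `V = v_scale · u · (X_a − X_b)` with `u ~ U(−1,1)` per
  dimension, so steps shrink as the population contracts;
* `h = h0 · exp(−gamma_h·t/T) · |N(0,1)|`, and the distance-adaptive rule
  is chosen per planet with probability `p_distance0 · exp(−gamma_h·t/T)`
  — exploration early, orbital exploitation late;
* `U`, `U1` are Bernoulli(1/2) masks; `X_a`, `X_b` are random distinct
  planets;
* bound handling is clamping (simplest deterministic repair), and a
  planet keeps a move only if its fitness does not worsen, so the
  best-so-far history is non-increasing by construction (elitism).

The published element-wise product with `U` and a scalar `Fg` is adopted
as written. On the 2-D sphere with the reference budget (population 10,
50 iterations) the implementation reaches a median best fitness far below
1e−2 over 20 seeds and beats equal-budget uniform random search; these
checks run in the test suite.

### Hyperparameter tuning

Search spaces follow the conventional ranges: DT `max_depth` 1–100,
`max_features` 0.1–1; SVM `C` 1–1000, `gamma` 0.1–1; KNN `n_neighbors`
1–100, Minkowski `p` 1–5; MLP hidden sizes `k1`, `k2` 10–100; RF/GBDT
`n_estimators` 1–100, `max_depth` 1–100, `max_features` 0.1–1. Integer
parameters are decoded by rounding and re-clamping. The fitness of a
position is the stratified k-fold CV misclassification rate at the decoded
parameters, with folds fixed per tuning run so fitness is a deterministic
function of position; evaluations are cached by decoded-parameter key,
since integer rounding makes many positions equivalent. `tune_model()`
defaults to 3 folds; the full pipeline uses 2 — with 80 training samples
per class a stratified half-split already ranks parameterisations stably,
and pilot runs showed identical tuned-model test accuracy at 2 and 3
folds while halving the evaluation cost of the 6 × 210-evaluation
experiment. Which data split the error rate is computed on is a free
choice; the package always uses CV folds inside the training split.

### Classifier engines

DT, RF use `ranger` (the DT family is a single ranger tree with
`mtry = round(max_features·p)`, reproducing per-split feature subsampling,
which recursive-partitioning fitters without `mtry` cannot express); SVM
uses `e1071` (RBF, `scale = FALSE` because inputs are already min–max
scaled); GBDT uses `xgboost` (softprob, histogram method); KNN is an
in-package Minkowski k-NN (integer `p` 1–5, vote-fraction probabilities,
ties broken by class order); the MLP is an in-package two-hidden-layer
ReLU/softmax network trained by full-batch Adam (40 epochs, learning rate
0.02, weight decay 1e−4) — no installed fitter provides the two-layer
`(k1, k2)` architecture the search space requires.

## Stacking

With base learners h_1..h_t and meta-learner f, the ensemble computes
y = f(h_1(x), …, h_t(x)). Training uses stratified k-fold (default k = 5)
out-of-fold construction: each base learner, fitted on k−1 folds, predicts
the held-out fold, so every training sample receives exactly one
out-of-fold prediction per learner; the meta-learner is trained on these
meta-features against the true labels, and base learners are refitted on
the full training split for inference. Meta-features default to label
predictions, one-hot encoded for the meta-learner (`probabilities` mode is
available). At inference there is no out-of-fold machinery: base
predictions on new data are encoded identically and passed to the
meta-learner.

The meta-learner is selected combinatorially among the six families:
candidates are scored by stratified k-fold CV *on the out-of-fold
meta-feature matrix*, built once and reused — a leakage-safe selection
confined to the training split that avoids refitting the base layer per
candidate. Ranking candidates on held-out test performance would leak the
test set into a modelling decision, so the package deliberately selects on
training data only and reports test-set scores of all candidate stacks
separately for comparison. Ties are broken by the fixed candidate order
DT, SVM, KNN, MLP, RF, GBDT.

## Evaluation

Overall accuracy is trace/total of the confusion matrix. Per-class
precision TP/(TP+FP), recall TP/(TP+FN) and F1 (harmonic mean) are
one-vs-rest; summary values are unweighted (macro) class means — with
balanced classes macro and weighted averages nearly coincide, and the
averaging convention is configurable in reporting. Zero-denominator
classes are reported as 0 with a warning. One-vs-rest AUC uses the
midrank formulation (equivalent to the trapezoidal ROC area under tied
scores); classes absent from the truth get `NA` and are excluded from the
macro mean with a warning. AUCs are computed from the meta-learner's class
probabilities. Relative improvement between two scores is
100·(value − reference)/reference, reported to two decimals.

## Synthetic data: what it emulates, and what it does not

No public seed dataset accompanies the reference design, and no
distributional description of the original data exists, so every
generator choice is a stand-in. The generator emulates the *statistical
structure the pipeline assumes*, not seed physics:

* **Spectra**: a constant (optionally polynomial) baseline; shared
  Gaussian bands (conserved biochemistry) plus per-class bands drawn from
  a pool with stride 1, so neighbouring varieties share three of their
  four discriminating bands and are genuinely confusable; per-sample
  band-height factors `exp(N(0, 0.25))` (biochemical heterogeneity,
  correlated across a band's channels); a per-sample multiplicative gain
  `N(1, 0.08)` (excitation-power fluctuation); iid channel noise
  (sd 0.1). Channels within 2.5 band widths of any class-specific band are
  recorded as ground-truth informative channels.
* **Image features**: class-conditional multivariate normals on
  heterogeneous instrument-realistic scales (pixel counts, 0–255
  intensities, unit ratios), with 15 of the 43 features shifted per class
  by ±3–5% of their baseline magnitude (about 0.5–0.8 within-class sd) in
  a fixed pattern; covariance defaults to diagonal.

Class separation was calibrated once so that a correctly implemented
pipeline clearly exceeds 80% held-out accuracy under the default
conditions (7 × 100 samples) — the end-to-end tests assert ≥ 0.80 and
that the stack is within 0.05 of the best single tuned learner. Passing
them demonstrates the pipeline's machinery end to end; it does *not*
demonstrate performance on real seeds: the generator has no fluorescence
background, cosmic spikes, within-band shape variation, feature
correlations across modalities, or label noise.

The generator does not render images; image features are generated
directly as numbers, since the pipeline consumes the numeric table.

## Numerical and protocol choices

* The spectral axis is the half-open grid [400, 1800) at 2 cm⁻¹ — exactly
  700 channels; an inclusive grid would have 701.
* Min–max statistics are fitted on the training split only and applied
  unchanged to test data; out-of-range transformed values are preserved
  (no clipping); constant training columns map to 0. SG smoothing is a
  fixed per-row linear filter (no statistics), so it may be applied before
  splitting without leakage; its edge handling is the filter's built-in
  local polynomial fit.
* CARS, KOA fitness and meta-learner selection see training rows only;
  `run_pipeline()` records which rows every fitted stage saw, and the
  suite asserts the test split is never touched.
* RMSECV pools squared errors over folds before the root; fold
  assignment is seeded. PLS components are capped by subset size and
  rank, with a warning when a requested count is infeasible.
* All randomness fans out from one global seed through a deterministic
  per-stage hash, so a rerun with an identical config reproduces
  predictions exactly.
* Degenerate inputs: all-zero ARS weights fall back to uniform sampling
  with a warning; non-finite KOA objective values are treated as +∞ with
  a warning; CARS stops early (logged) if fewer than two features remain.
* Problem sizes in the shipped experiments: the end-to-end study runs the
  default 7 × 100 dataset with KOA budget 10 × 20 per family (the
  reference budget is 10 × 50; `koa_config()` keeps that default); the
  selection-recovery study uses a 200-channel axis, 3 × 70 samples and 20
  replicate runs; sphere convergence uses the full 10 × 50 budget.

## Known limitations

* The MLP is full-batch Adam at a fixed epoch budget — adequate for these
  problem sizes, not a general-purpose deep-learning fitter.
* SVM class probabilities (Platt scaling) involve libsvm's internal
  randomisation; label predictions are deterministic, probability values
  may vary in the last digits between sessions.
* Integer-coded PLS imposes an arbitrary class ordering; it is the
  classic CARS practice and works well here, but one-hot encoding is the
  principled alternative and is available.
* CARS selection sizes on synthetic data are data-dependent; the package
  makes no claim of reproducing any particular published subset.
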