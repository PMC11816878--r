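---
title: "Methods: texture/deep feature fusion, Harris Hawks selection, and LSTM classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: texture/deep feature fusion, Harris Hawks selection, and LSTM classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The pipeline

`texhawk` implements a hybrid binary classifier for grayscale images, aimed
at the kind of two-class problems that arise in neuroimaging (diseased vs
control MRI slices). The stages are:

1. **Preprocessing** — Gaussian smoothing parameterized by FWHM in
   millimetres (`fwhm_to_sigma()` uses the identity
   $\mathrm{FWHM} = 2\sqrt{2\ln 2}\,\sigma$), followed by resizing to the
   feature backend's input size, then a stratified 70/30 train/test split.
2. **Feature extraction** — 20 gray-level co-occurrence matrix (GLCM)
   texture statistics fused with 20 features from a convolutional backend,
   giving a 40-column feature table.
3. **Wrapper feature selection** — Harris Hawks Optimization (HHO) over
   $[0,1]^{40}$, with positions thresholded into binary masks and scored by
   $\mathrm{cost}(m) = w_1\,\mathrm{Err}(m) + w_2\, m/n$, where
   $\mathrm{Err}$ is the cross-validated misclassification rate of a small
   perceptron on the masked columns.
4. **Classification** — a long short-term memory (LSTM) network over the
   selected features, trained by full-batch gradient descent on binary
   cross-entropy, with an affine-plus-sigmoid read-out of the final hidden
   state.
5. **Evaluation** — confusion counts and percentage metrics.

Selection, standardization, and training see only the training split; the
test split is touched once, at evaluation.

## GLCM texture features

`compute_glcm()` counts ordered pixel pairs at an offset given by a distance
$d$ and an angle from $\{0, 45, 90, 135\}$ degrees, using the common
convention (rows increasing downward): $0^\circ = (0, +d)$,
$45^\circ = (-d, +d)$, $90^\circ = (-d, 0)$, $135^\circ = (-d, -d)$.
Matrices are symmetrized and normalized by default, the dominant Haralick
convention. Five statistics are computed per matrix:

* energy $\sum_{ij} p_{ij}^2$,
* contrast $\sum_{ij} (i-j)^2 p_{ij}$,
* homogeneity $\sum_{ij} p_{ij} / (1 + |i-j|)$,
* correlation $\sum_{ij}(i-\mu_i)(j-\mu_j)p_{ij}/(\sigma_i\sigma_j)$, and
* entropy $-\sum_{ij} p_{ij}\log_2 p_{ij}$ (with $0\log 0 = 0$).

The default texture vector uses $d = 1$, all four angles, and all five
statistics: exactly 20 named features. Which 20 of the possible
(distance × angle × statistic) combinations make the best set is an open
design choice; this one is symmetric in orientation and uses every statistic
once. Correlation of a degenerate (constant-marginal) matrix is reported as
0, since there is no linear dependence to measure; homogeneity and energy of
a constant image are exactly 1 and contrast exactly 0.

## The deep-feature backend

The deep stage is a *contract*, not a fixed network: anything that maps a
preprocessed image to a fixed-length vector can stand behind
`extract_deep_features()`. The bundled reference backend
(`seeded_stack_backend()`) is an untrained convolutional stack with seeded
random filters: normalize to $[0,1]$, remove the image mean (making features
invariant to constant intensity shifts), apply each $3\times3$ filter with a
valid convolution and ReLU, pool each response map to its mean and standard
deviation, and project the pooled vector to 20 features with a fixed seeded
linear map. It is deterministic, dependency-free, and honest about not being
a trained network; a pretrained embedding reduced to 20 dimensions (e.g.
global average pooling followed by a fixed projection) plugs into the same
contract. How a 2048-dimensional pretrained embedding best becomes 20
features is genuinely underdetermined; the fixed seeded projection is the
simplest reproducible answer.

## Harris Hawks Optimization

`hho_minimize()` implements the printed update rules of HHO as a continuous
minimizer. Per iteration the escape energy $E = 2E_0(1 - t/T)$ dispatches
each hawk:

* $|E| \ge 1$: exploration — perch relative to a random hawk
  ($X' = X_{\mathrm{rand}} - r_1 |X_{\mathrm{rand}} - 2 r_2 X|$) or relative
  to the prey and centroid
  ($X' = (X_{\mathrm{rabbit}} - X_m) - r_3(LB + r_4(UB - LB))$);
* $|E| \ge 0.5$ (and $r \ge 0.5$): soft besiege
  $X' = \Delta X - E\,|J X_{\mathrm{rabbit}} - X|$ with
  $\Delta X = X_{\mathrm{rabbit}} - X$;
* $|E| < 0.5$ (and $r \ge 0.5$): hard besiege
  $X' = X_{\mathrm{rabbit}} - E\,|\Delta X|$;
* $r < 0.5$: rapid dive
  $X' = X_{\mathrm{rabbit}} - E\,|J X_{\mathrm{rabbit}} - X_m|$, accepted
  only if it improves the hawk's cost (greedy acceptance, which preserves
  best-so-far monotonicity).

Design choices where the source formulation is ambiguous or silent:

* **$E_0$ schedule.** The stated initial value of $E$ is 2, but the energy
  is also described as decreasing *randomly* from 2 to 0. The default
  resamples $E_0 \sim U(-1, 1)$ each iteration (the original HHO
  convention, consistent with the random decay and the envelope
  $|E| \le 2$); `e0_mode = "fixed"` keeps $E_0 = 1$ so that $E$ starts at
  exactly 2 and decays deterministically.
* **$J$** is resampled per update as $2(1 - U(0,1)) \in [0, 2]$.
* **Lévy dives.** The original algorithm's Lévy-flight progressive dives are
  not part of the printed update set; the default omits them, and
  `levy_dives = TRUE` restores the operator as a second greedy candidate.
* **Bounds** are enforced by clamping to $[LB, UB]$ before evaluation.
* Non-finite costs reject the candidate with a warning rather than
  propagate.

On the 5-dimensional sphere with population 30 and 100 iterations the
optimizer reaches far lower costs than equal-budget uniform random search;
the test suite and the acceptance script compute this benchmark.

## Wrapper selection and its cost

Hawk positions in $[0,1]^n$ become masks by thresholding at 0.5 (an
all-zero mask is repaired to its largest coordinate, so every evaluated mask
selects at least one feature). The cost is
$w_1\,\mathrm{Err} + w_2\,m/n$ with defaults $w_1 = 0.99$, $w_2 = 0.01$ —
the usual wrapper convention that keeps error dominant. The sparsity ratio
is oriented as $m/n$ (selected over total) so that minimization favors
fewer features.

The error term is the validation misclassification rate of a one-hidden-
layer perceptron (`nnet`, default width 8, 60 iterations, weight decay
$10^{-3}$) trained on the masked columns. Validation is **stratified 5-fold
cross-validation, averaged over 2 repeated fold assignments**, rather than a
single small holdout. The reason is resolution: with a 30% holdout of a
200-sample table the error estimate is quantized at 1/60 and is frequently
exactly zero for several near-perfect masks at once, so the cost degenerates
to the sparsity term and selection among strong masks becomes arbitrary.
Scoring every sample once per fold assignment (and averaging assignments)
gives the error term a 1/200-scale resolution at modest extra cost. Costs
are cached by mask bits, since the optimizer revisits subsets often, and the
fold assignment is computed once per table so all masks are scored on the
same partition.

A structural limitation worth knowing: when a strict subset of the
informative columns already separates the classes with zero *empirical*
validation error — which happens regularly once the per-column
between-class shift is around 3 standard deviations and $n \approx 200$ —
the cost's optimum genuinely drops the remaining informative columns, since
only the sparsity term still differentiates. Planted-recovery experiments at
that effect size therefore typically recover a majority (3–4) of 5 planted
columns in a compact mask rather than all 5. This is a property of the
error-plus-sparsity objective itself, not of the optimizer.

## The LSTM classifier

The cell follows the standard gate equations
$f = \sigma(W_f x + U_f h + b_f)$, $i = \sigma(W_i x + U_i h + b_i)$,
$o = \sigma(W_o x + U_o h + b_o)$, $\tilde c = \tanh(W_c x + U_c h + b_c)$,
$c' = f \circ c + i \circ \tilde c$, with output rule
$h' = o \circ \tanh(c')$. The source formulation prints the output rule as
$h = \tanh(C) + O$, which is inconsistent with gated output (it makes $h$
unbounded); the standard multiplicative rule is the default and
`paper_literal = TRUE` reproduces the printed form for comparison. The input
gate, whose defining equation is not printed there, is defined by symmetry
with the forget and output gates.

Flat feature vectors are presented to the recurrence as a sequence of
chunks: with the default chunk length 8, a fused 40-feature vector becomes 5
time steps (zero-padded when the count is not a multiple). Training is plain
gradient descent — full-batch by default, mini-batch via `batch_size` —
with learning rate 1 on the batch-mean binary cross-entropy for 300 epochs
(hidden size 16), using backpropagation through time
implemented in the package and checked against finite differences in the
test suite. Everything is seeded: identical configuration and seed give
bit-identical weights. Prediction maps probability $\ge 0.5$ to the positive
class.

## Evaluation metrics and naming

The positive class is the diseased ("malignant") class, label 1. Metrics in
percent: accuracy $(TP+TN)/n$, sensitivity $TP/(TP+FN)$, precision
$TP/(TP+FP)$, specificity $TN/(TN+FP)$. The source formulation labels
$TN/(TN+FP)$ — the textbook specificity kernel — as "precision"; the report
carries that value under both `paper_precision` and `specificity`, next to
the standard precision, so the mislabel is reproduced transparently rather
than silently. Metrics with a zero denominator are reported as `NA`
(undefined), never as 0: small fixtures hit these cases.

## Synthetic fixtures: what they emulate and what they do not

`make_textured_image()` builds class-specific textures by smoothing white
Gaussian noise to a spatial correlation length (`blob_scale`), rescaling to
unit spread, mapping onto the gray range around `base_level` (amplitude
fixed at (levels−1)/5, so about ±2.5 within-image standard deviations span
half the range), adding pixel noise, and quantizing. This gives direct,
controllable co-occurrence statistics — smaller `blob_scale` means higher
GLCM contrast and lower homogeneity — without mimicking anatomy.
`make_planted_feature_table()` plants Gaussian informative columns with
class-dependent means ($\pm$ effect/2, unit within-class spread) among pure
noise columns and records their identity for recovery tests.

Passing tests on these fixtures show that the machinery is correct and that
the pipeline detects genuine texture or mean-shift signal; they do not show
anything about anatomical plausibility, 3-D structure, scanner artifacts, or
the class overlap of real MRI cohorts. Access-restricted imaging datasets
are deliberately out of scope.

## Problem sizes and defaults

Package defaults mirror the reference protocol: 4 mm FWHM at 1 mm voxels,
224 × 224 target size, 70% training fraction, HHO population 30 for 100
iterations, initial energy scale 2, 20 + 20 = 40 fused features. The test
suite and acceptance script run the same machinery at desk scale — 64 × 64
images, 50 images per class, GLCM at 32 levels, selection with population 12
for 15 iterations, 3–5 replicate seeds — sizes chosen so the whole study
re-runs in minutes on one CPU while leaving every qualitative property
(separability, chance-level nulls, determinism, recovery behavior) intact.

## Known limitations

* The bundled deep backend is untrained; its features separate texture
  classes but carry no learned semantics.
* Wrapper selection inherits the winner's-curse bias of minimizing a noisy
  error estimate over many masks; repeated CV damps but does not remove it.
* Training is plain gradient descent without adaptive step sizes; very
  ill-conditioned feature sets may need a different learning rate than the
  default.
* Only binary classification is supported, matching the benign/malignant
  framing.
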