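# texhawk

Binary classification of grayscale images — the diseased-vs-control setting
of Alzheimer's MRI studies — through a hybrid pipeline that fuses classical
texture statistics with deep-style convolutional features, selects the
informative subset with a swarm optimizer, and classifies with a recurrent
network. Everything is testable at the desk: synthetic fixture generators
stand in for access-restricted imaging cohorts.

## What it computes

**Features.** For each image, 20 gray-level co-occurrence matrix (GLCM)
texture statistics — energy Σp², contrast Σ(i−j)²p, homogeneity
Σp/(1+|i−j|), correlation, entropy, over distance 1 and angles
0°/45°/90°/135° — are fused with 20 features from a pluggable convolutional
backend (`deep:*` then `glcm:*`, 40 in total).

**Selection.** Harris Hawks Optimization (HHO) searches `[0,1]^40`; hawk
positions are thresholded into feature masks and scored by the wrapper cost

    cost(mask) = w1 · Error(mask) + w2 · m/n,      w1 = 0.99, w2 = 0.01

where `Error` is the cross-validated misclassification rate of a small
perceptron on the masked columns, `m` the selected count and `n` the total.
The escape-energy schedule `E = 2·E0·(1 − t/T)` switches hawks between
exploration (|E| ≥ 1), soft besiege (|E| ≥ 0.5), hard besiege (|E| < 0.5),
and greedy rapid dives.

**Classification.** An LSTM (standard forget/input/output gates,
`h = o ∘ tanh(c)` output rule) consumes the selected features as a sequence
of 8-feature chunks and is trained by seeded gradient descent on binary
cross-entropy. Metrics are reported in percent from confusion counts:
accuracy, sensitivity TP/(TP+FN), precision TP/(TP+FP), and specificity
TN/(TN+FP) — the latter also exposed as `paper_precision`, since the
formulation this pipeline follows labels that kernel "precision".

See `vignettes/texture-hho-lstm.Rmd` for the full method description and
design rationale.

## Worked example

```r
library(texhawk)

# two texture classes: coarse (label 0) vs smooth (label 1) blobs
specs <- list(texture_class_spec(0, 16, 2, 1),
              texture_class_spec(1, 16, 16, 1))
dataset <- make_image_dataset(25, specs, size = 64, levels = 32, seed = 42)

# texture statistics of one coarse-class image
img <- dataset[[1]]$image
round(unlist(glcm_statistics(compute_glcm(img, glcm_config(levels = 32)))), 3)
#>      energy    contrast homogeneity correlation     entropy
#>       0.006       6.564       0.455       0.913       7.892

# full pipeline: split, extract+fuse, HHO selection, LSTM, evaluate
cfg <- run_config(seed = 7,
                  preprocess = preprocess_config(target_size = c(64, 64)),
                  glcm = glcm_config(levels = 32),
                  hho = hho_params(n_pop = 12, n_iter = 15))
result <- run_pipeline(dataset, cfg)
result$report
#> Classification report (positive = malignant/AD)
#>   n = 15  [TP 8  TN 7  FP 0  FN 0]
#>   accuracy     100.00%
#>   sensitivity  100.00%
#>   precision    100.00%
#>   specificity  100.00%  (reported as precision in the source formulation)

names(which(result$selection$mask == 1))
#> [1] "glcm:d1_a90_energy"
```

The low energy (0.006) and high contrast (6.56) of the first image are the
signature of coarse texture: intensity pairs spread over many GLCM cells
with frequent large level jumps. The two classes differ enough in their
co-occurrence structure that the wrapper cost settles on a single vertical
energy feature and the classifier separates the held-out 15 images
perfectly. On harder data the selected mask is larger and the metrics drop
accordingly; the `selection$history` data frame records the optimizer's
convergence.

A command-line interface with `synth` / `table` / `features` / `select` /
`train` / `evaluate` / `run` subcommands is installed at
`system.file("exec/texhawk", package = "texhawk")`.

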