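# Wrapper feature selection: hawk positions in [0, 1]^n are thresholded into
# binary feature masks and scored by a cost that mixes the validation error
# of a small perceptron with a sparsity penalty:
#   cost(mask) = w1 * Error(mask) + w2 * m / n
# where m features of n are selected.

#' Binarize a continuous position into a feature mask
#'
#' Bit i is 1 iff `position[i] >= threshold`. An all-zero mask is repaired by
#' setting the single largest coordinate, so every evaluated mask selects at
#' least one feature.
#'
#' @param position Numeric vector in `[0, 1]`.
#' @param threshold Cut point (default 0.5).
#' @return Integer 0/1 vector.
#' @export
binarize <- function(position, threshold = 0.5) {
  check_number(threshold, "threshold")
  bits <- as.integer(position >= threshold)
  if (sum(bits) == 0L) bits[which.max(position)] <- 1L
  bits
}

#' Selection cost weights
#'
#' Weights are normalized to sum to 1 at construction. The defaults
#' (w1 = 0.99, w2 = 0.01) keep the classification-error term dominant, the
#' usual wrapper-selection convention.
#'
#' @param w1 Error weight (>= 0).
#' @param w2 Sparsity weight (>= 0).
#' @return List of class `"selection_weights"`.
#' @export
selection_weights <- function(w1 = 0.99, w2 = 0.01) {
  check_number(w1, "w1", lower = 0)
  check_number(w2, "w2", lower = 0)
  if (w1 + w2 == 0) stop_arg("at least one weight must be positive")
  s <- w1 + w2
  structure(list(w1 = w1 / s, w2 = w2 / s), class = "selection_weights")
}

#' Configuration of the mask evaluator network
#'
#' The evaluator is a one-hidden-layer perceptron ([nnet::nnet]) trained on
#' the masked columns of the table; its validation misclassification rate is
#' the error term of the selection cost. Validation is stratified k-fold
#' cross-validation by default (every sample is scored once, which gives the
#' error term enough resolution to separate near-perfect masks at desk
#' scale); a single stratified holdout is available as the cheaper
#' alternative. Folds/splits and weight initialization are seeded, so the
#' cost is deterministic in (mask, table, seed).
#'
#' @param hidden Hidden layer width (default 8).
#' @param maxit Training iterations (default 60).
#' @param decay Weight decay (default 1e-3).
#' @param validation `"cv"` (default) or `"holdout"`.
#' @param folds Fold count for cross-validation (default 5).
#' @param repeats Number of repeated fold assignments averaged in CV mode
#'   (default 2). Repetition damps the winner's-curse effect of minimizing a
#'   noisy error estimate over many candidate masks.
#' @param holdout Validation fraction for holdout mode (default 0.3).
#' @param seed RNG seed (default 1).
#' @return List of class `"evaluator_config"`.
#' @export
evaluator_config <- function(hidden = 8L, maxit = 60L, decay = 1e-3,
                             validation = c("cv", "holdout"), folds = 5L,
                             repeats = 2L, holdout = 0.3, seed = 1L) {
  check_number(hidden, "hidden", lower = 1)
  check_number(maxit, "maxit", lower = 1)
  check_number(decay, "decay", lower = 0)
  validation <- match.arg(validation)
  check_number(folds, "folds", lower = 2)
  check_number(repeats, "repeats", lower = 1)
  check_number(holdout, "holdout")
  if (holdout <= 0 || holdout >= 1) stop_arg("`holdout` must be in (0, 1)")
  structure(list(hidden = as.integer(hidden), maxit = as.integer(maxit),
                 decay = decay, validation = validation,
                 folds = as.integer(folds), repeats = as.integer(repeats),
                 holdout = holdout, seed = seed),
            class = "evaluator_config")
}

# Precompute the validation structure once per table (stratified, seeded);
# shared across all masks so costs are comparable. Returns a list of
# (train_idx, val_idx) pairs: k pairs for CV, one for holdout.
evaluator_split <- function(table, evaluator) {
  y <- as_binary_labels(table$label)
  if (length(unique(y)) < 2L) stop_arg("`table` must contain both classes")
  if (evaluator$validation == "holdout") {
    sp <- split_dataset(as.list(seq_along(y)),
                        train_fraction = 1 - evaluator$holdout,
                        seed = evaluator$seed, stratified = TRUE, labels = y)
    return(list(list(train_idx = sp$train_idx, val_idx = sp$test_idx)))
  }
  k <- evaluator$folds
  out <- list()
  for (rep_i in seq_len(evaluator$repeats)) {
    fold <- with_seed(derive_seed(evaluator$seed, rep_i), {
      f <- integer(length(y))
      for (cl in unique(y)) {
        idx <- which(y == cl)
        f[idx] <- sample(rep_len(seq_len(k), length(idx)))
      }
      f
    })
    out <- c(out, lapply(seq_len(k), function(i) {
      list(train_idx = which(fold != i), val_idx = which(fold == i))
    }))
  }
  out
}

#' Wrapper selection cost of a feature mask
#'
#' `cost = w1 * Error(mask) + w2 * m / n` where `Error` is the evaluator
#' network's validation misclassification rate using only the masked
#' columns, `m` the number of selected features and `n` the total. The
#' error and sparsity components are attached as attributes for auditing.
#'
#' @param mask Integer 0/1 vector over the feature columns (at least one
#'   bit set).
#' @param table Feature table (data frame, `label` column, both classes).
#' @param weights A [selection_weights()].
#' @param evaluator An [evaluator_config()].
#' @param split Optional precomputed [evaluator_split()] (an optimization
#'   for repeated calls on the same table).
#' @return Scalar cost with attributes `error`, `sparsity`, `m`.
#' @export
selection_cost <- function(mask, table, weights = selection_weights(),
                           evaluator = evaluator_config(), split = NULL) {
  feat_cols <- setdiff(names(table), "label")
  n <- length(feat_cols)
  if (length(mask) != n) stop_arg("`mask` length must equal the feature count")
  mask <- as.integer(mask)
  m <- sum(mask)
  if (m < 1L) stop_arg("`mask` must select at least one feature (repair upstream)")
  y <- as_binary_labels(table$label)
  if (length(unique(y)) < 2L) stop_arg("`table` must contain both classes")
  err <- if (weights$w1 == 0) {
    0  # evaluator not consulted when the error term carries no weight
  } else {
    if (is.null(split)) split <- evaluator_split(table, evaluator)
    X <- as.matrix(table[feat_cols])[, mask == 1L, drop = FALSE]
    fold_errs <- vapply(split, function(sp) {
      tr <- sp$train_idx; va <- sp$val_idx
      fit <- with_seed(evaluator$seed, {
        nnet::nnet(x = X[tr, , drop = FALSE], y = y[tr],
                   size = evaluator$hidden, entropy = TRUE,
                   maxit = evaluator$maxit, decay = evaluator$decay,
                   trace = FALSE)
      })
      pred <- as.integer(stats::predict(fit, X[va, , drop = FALSE]) >= 0.5)
      mean(pred != y[va])
    }, numeric(1))
    # CV folds all have (near-)equal size; the plain mean is their pooled rate
    mean(fold_errs)
  }
  cost <- weights$w1 * err + weights$w2 * (m / n)
  structure(cost, error = err, sparsity = m / n, m = m)
}

#' Select features with Harris Hawks Optimization
#'
#' Runs [hho_minimize()] over `[0, 1]^n` with
#' `selection_cost(binarize(x))` as the objective. Costs are cached by mask
#' bits (HHO revisits subsets often), and the best mask ever evaluated is
#' returned. Reproducible under the HHO seed.
#'
#' @param table Feature table with a `label` column and both classes.
#' @param hho An [hho_params()] with bounds `[0, 1]`.
#' @param weights A [selection_weights()].
#' @param evaluator An [evaluator_config()].
#' @return List of class `"hho_selection"`: `mask` (named 0/1 vector),
#'   `cost`, `error`, `history`, `n_evals`, `n_unique_masks`.
#' @export
hho_select_features <- function(table, hho = hho_params(),
                                weights = selection_weights(),
                                evaluator = evaluator_config()) {
  feat_cols <- setdiff(names(table), "label")
  n <- length(feat_cols)
  if (n < 1L) stop_arg("`table` has no feature columns")
  if (any(!is.finite(as.matrix(table[feat_cols])))) {
    stop_arg("`table` must be finite")
  }
  split <- evaluator_split(table, evaluator)
  cache <- new.env(parent = emptyenv())
  objective <- function(x) {
    bits <- binarize(x)
    key <- paste(bits, collapse = "")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    v <- as.numeric(selection_cost(bits, table, weights, evaluator,
                                   split = split))
    cache[[key]] <- v
    v
  }
  res <- hho_minimize(objective, dim = n, params = hho)
  mask <- binarize(res$best_position)
  names(mask) <- feat_cols
  final <- selection_cost(mask, table, weights, evaluator, split = split)
  structure(list(mask = mask, cost = as.numeric(final),
                 error = attr(final, "error"), history = res$history,
                 n_evals = res$n_evals,
                 n_unique_masks = length(ls(cache))),
            class = "hho_selection")
}

#' Write a selected mask as a two-column CSV
#'
#' @param selection An [hho_select_features()] result (or named 0/1 vector).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(selection, path) {
  mask <- if (inherits(selection, "hho_selection")) selection$mask else selection
  utils::write.csv(data.frame(feature = names(mask),
                              selected = as.integer(mask)),
                   path, row.names = FALSE)
  invisible(path)
}
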