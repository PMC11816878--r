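# Confusion-matrix metrics and end-to-end pipeline orchestration.
#
# The positive class is "malignant" (the diseased class, label 1); label 0
# is "benign" (control). Metrics are reported as percentages. Note on
# naming: the source formulation of this pipeline defines its "precision"
# as TN / (TN + FP), which is the textbook specificity kernel; both that
# value (as `paper_precision` and `specificity`) and the standard precision
# TP / (TP + FP) are reported, clearly named.

#' Tally confusion counts
#'
#' @param truth Binary ground-truth labels (0/1).
#' @param predicted Binary predicted labels, same length.
#' @return List of class `"confusion_counts"` with `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(truth, predicted) {
  truth <- as_binary_labels(truth, "truth")
  predicted <- as_binary_labels(predicted, "predicted")
  if (length(truth) != length(predicted)) {
    stop_arg("`truth` and `predicted` must have equal length")
  }
  structure(list(tp = sum(truth == 1L & predicted == 1L),
                 tn = sum(truth == 0L & predicted == 0L),
                 fp = sum(truth == 0L & predicted == 1L),
                 fn = sum(truth == 1L & predicted == 0L)),
            class = "confusion_counts")
}

# A ratio in percent; zero denominators yield NA (undefined, never 0).
pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den

#' Classification metrics from confusion counts
#'
#' accuracy = (TP+TN)/(TP+TN+FP+FN) * 100;
#' sensitivity (recall) = TP/(TP+FN) * 100;
#' precision = TP/(TP+FP) * 100;
#' specificity = TN/(TN+FP) * 100, also reported as `paper_precision` (see
#' the module note). Metrics with a zero denominator are `NA` (undefined).
#'
#' @param counts A [confusion_counts()].
#' @return List of class `"classification_report"` with the metrics (in
#'   percent), `counts`, and `n`.
#' @export
classification_metrics <- function(counts) {
  if (!inherits(counts, "confusion_counts")) {
    stop_arg("`counts` must come from confusion_counts()")
  }
  with(counts, {
    n <- tp + tn + fp + fn
    spec <- pct(tn, tn + fp)
    structure(list(
      accuracy = pct(tp + tn, n),
      sensitivity = pct(tp, tp + fn),
      precision = pct(tp, tp + fp),
      specificity = spec,
      paper_precision = spec,
      counts = counts, n = n), class = "classification_report")
  })
}

#' @export
print.classification_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.2f%%", v)
  cat("Classification report (positive = malignant/AD)\n")
  cat(sprintf("  n = %d  [TP %d  TN %d  FP %d  FN %d]\n", x$n,
              x$counts$tp, x$counts$tn, x$counts$fp, x$counts$fn))
  cat("  accuracy    ", fmt(x$accuracy), "\n")
  cat("  sensitivity ", fmt(x$sensitivity), "\n")
  cat("  precision   ", fmt(x$precision), "\n")
  cat("  specificity ", fmt(x$specificity), " (reported as precision in the",
      "source formulation)\n")
  invisible(x)
}

#' Full pipeline configuration
#'
#' Bundles the stage configurations and a single global seed from which
#' every stage seed is derived. Defaults mirror the reference protocol
#' (4 mm FWHM smoothing, 70/30 split, HHO population 30 for 100 iterations)
#' except where noted in each sub-config.
#'
#' @param seed Global RNG seed (default 1).
#' @param preprocess A [preprocess_config()].
#' @param glcm A [glcm_config()].
#' @param backend A [seeded_stack_backend()].
#' @param hho An [hho_params()].
#' @param weights A [selection_weights()].
#' @param evaluator An [evaluator_config()].
#' @param classifier A [classifier_config()].
#' @param out_dir Optional directory for artifacts (report, mask, history,
#'   manifest); `NULL` writes nothing.
#' @return List of class `"run_config"`.
#' @export
run_config <- function(seed = 1L,
                       preprocess = preprocess_config(),
                       glcm = glcm_config(levels = 32L),
                       backend = seeded_stack_backend(),
                       hho = hho_params(),
                       weights = selection_weights(),
                       evaluator = evaluator_config(),
                       classifier = classifier_config(),
                       out_dir = NULL) {
  structure(list(seed = seed, preprocess = preprocess, glcm = glcm,
                 backend = backend, hho = hho, weights = weights,
                 evaluator = evaluator, classifier = classifier,
                 out_dir = out_dir),
            class = "run_config")
}

# Stable fingerprint of a config (text digest of its deparsed value).
config_fingerprint <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config[setdiff(names(config), "out_dir")]), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full classification pipeline
#'
#' Stages: stratified train/test split -> preprocessing (smooth, resize) ->
#' deep + texture extraction and fusion -> per-feature standardization (fit
#' on the training split only) -> HHO wrapper feature selection (training
#' split only) -> LSTM training -> test-set evaluation. Reproducible under
#' the global seed; every stage seed is derived from it.
#'
#' @param dataset List of `list(image=, label=)` items (e.g. from
#'   [make_image_dataset()]), or a feature table data frame with a `label`
#'   column (images stages are then skipped).
#' @param config A [run_config()].
#' @return List of class `"pipeline_result"`: `report`
#'   (a [classification_metrics()] result), `selection`, `model`,
#'   `standardizer`, `split`, `manifest`.
#' @export
run_pipeline <- function(dataset, config = run_config()) {
  seed <- config$seed
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_arg("pipeline stage `%s` failed: %s", name, conditionMessage(e))
    })
  }
  if (is.data.frame(dataset)) {
    table <- dataset
    labels <- as_binary_labels(table$label)
  } else {
    table <- stage("features", {
      ds <- lapply(dataset, function(item) {
        list(image = preprocess_image(item$image, config$preprocess),
             label = item$label)
      })
      extract_feature_table(ds, backend = config$backend, glcm = config$glcm,
                            preprocess = NULL)
    })
    labels <- as_binary_labels(table$label)
  }
  feat_cols <- setdiff(names(table), "label")

  split <- stage("split", split_dataset(
    as.list(seq_len(nrow(table))),
    train_fraction = config$preprocess$train_fraction,
    seed = derive_seed(seed, 1L), stratified = TRUE, labels = labels))
  tr <- split$train_idx; te <- split$test_idx

  X <- as.matrix(table[feat_cols])
  std <- stage("standardize", fit_standardizer(X[tr, , drop = FALSE]))
  Xs <- apply_standardizer(X, std)
  train_tab <- as.data.frame(Xs[tr, , drop = FALSE], check.names = FALSE)
  train_tab$label <- labels[tr]

  hho <- config$hho; hho$seed <- derive_seed(seed, 2L)
  evaluator <- config$evaluator; evaluator$seed <- derive_seed(seed, 3L)
  selection <- stage("select", hho_select_features(
    train_tab, hho = hho, weights = config$weights, evaluator = evaluator))
  sel <- which(selection$mask == 1L)

  cls <- config$classifier; cls$seed <- derive_seed(seed, 4L)
  model <- stage("train", train_classifier(
    Xs[tr, sel, drop = FALSE], labels[tr], config = cls))

  pred <- stage("evaluate", predict(model, Xs[te, sel, drop = FALSE]))
  report <- classification_metrics(confusion_counts(labels[te], pred$label))

  manifest <- list(seed = seed, config_fingerprint = config_fingerprint(config),
                   n_train = length(tr), n_test = length(te),
                   n_features = length(feat_cols),
                   n_selected = length(sel),
                   preprocess_order = "smooth_then_resize",
                   package_version = as.character(utils::packageVersion("texhawk")))
  result <- structure(list(report = report, selection = selection,
                           model = model, standardizer = std, split = split,
                           manifest = manifest),
                      class = "pipeline_result")
  if (!is.null(config$out_dir)) {
    write_pipeline_artifacts(result, config$out_dir)
  }
  result
}

#' Write pipeline artifacts to a directory
#'
#' Writes `report.json` (metrics + counts), `selected_mask.csv`,
#' `history.csv` (HHO convergence), and `manifest.json` (seed, config
#' fingerprint, sizes). Output is byte-stable for identical runs.
#'
#' @param result A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_artifacts <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rep <- result$report
  jsonlite::write_json(
    list(accuracy = rep$accuracy, sensitivity = rep$sensitivity,
         precision = rep$precision, specificity = rep$specificity,
         paper_precision = rep$paper_precision,
         counts = unclass(rep$counts), n = rep$n),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  write_mask(result$selection, file.path(dir, "selected_mask.csv"))
  utils::write.csv(result$selection$history, file.path(dir, "history.csv"),
                   row.names = FALSE)
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
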