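test_that("confusion counts tally the four cells correctly", {
  y <- c(rep(1, 6), rep(0, 4))
  perfect <- confusion_counts(y, y)
  expect_identical(unclass(perfect)[c("tp", "tn", "fp", "fn")],
                   list(tp = 6L, tn = 4L, fp = 0L, fn = 0L))
  allpos <- confusion_counts(y, rep(1, 10))
  expect_identical(allpos$tp, 6L); expect_identical(allpos$fp, 4L)
  expect_identical(allpos$tn, 0L); expect_identical(allpos$fn, 0L)
  expect_error(confusion_counts(y, y[1:5]), "equal length")
  expect_error(confusion_counts(c(0, 2), c(0, 1)), "binary")
})

test_that("confusion counts match a brute-force per-sample tally", {
  set.seed(77)
  for (k in 1:20) {
    n <- sample(5:50, 1)
    y <- sample(0:1, n, replace = TRUE)
    p <- sample(0:1, n, replace = TRUE)
    cc <- confusion_counts(y, p)
    tp <- tn <- fp <- fn <- 0L
    for (i in seq_len(n)) {
      if (y[i] == 1 && p[i] == 1) tp <- tp + 1L
      if (y[i] == 0 && p[i] == 0) tn <- tn + 1L
      if (y[i] == 0 && p[i] == 1) fp <- fp + 1L
      if (y[i] == 1 && p[i] == 0) fn <- fn + 1L
    }
    expect_identical(c(cc$tp, cc$tn, cc$fp, cc$fn), c(tp, tn, fp, fn))
    expect_identical(cc$tp + cc$tn + cc$fp + cc$fn, n)
  }
})

test_that("metrics reproduce the worked four-count example", {
  counts <- confusion_counts(c(rep(1, 55), rep(0, 45)),
                             c(rep(1, 50), rep(0, 5), rep(1, 5), rep(0, 40)))
  expect_identical(c(counts$tp, counts$tn, counts$fp, counts$fn),
                   c(50L, 40L, 5L, 5L))
  rep_ <- classification_metrics(counts)
  expect_equal(rep_$accuracy, 90.0)
  expect_equal(rep_$sensitivity, 100 * 50 / 55, tolerance = 1e-10)  # ~90.91
  expect_equal(rep_$paper_precision, 100 * 40 / 45, tolerance = 1e-10)  # ~88.89
  expect_equal(rep_$specificity, rep_$paper_precision)
  expect_equal(rep_$precision, 100 * 50 / 55, tolerance = 1e-10)  # ~90.91
})

test_that("perfect prediction yields 100% everywhere; zero denominators are undefined", {
  y <- c(rep(1, 7), rep(0, 3))
  rep_ <- classification_metrics(confusion_counts(y, y))
  expect_equal(rep_$accuracy, 100)
  expect_equal(rep_$sensitivity, 100)
  expect_equal(rep_$precision, 100)
  expect_equal(rep_$specificity, 100)
  # no positives at all: sensitivity undefined, not zero
  none <- classification_metrics(confusion_counts(rep(0, 5), rep(0, 5)))
  expect_true(is.na(none$sensitivity))
  expect_true(is.na(none$precision))
  expect_equal(none$accuracy, 100)
})

test_that("metric identities hold on random fixtures", {
  set.seed(55)
  for (k in 1:20) {
    n <- sample(10:80, 1)
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    p <- sample(0:1, n, replace = TRUE)
    cc <- confusion_counts(y, p)
    m <- classification_metrics(cc)
    expect_equal(m$accuracy * m$n / 100, cc$tp + cc$tn, tolerance = 1e-9)
    # swapping the positive/negative convention swaps the paired metrics
    cc_sw <- confusion_counts(1 - y, 1 - p)
    m_sw <- classification_metrics(cc_sw)
    expect_identical(cc_sw$tp, cc$tn); expect_identical(cc_sw$fp, cc$fn)
    if (!is.na(m$sensitivity) && !is.na(m_sw$specificity)) {
      expect_equal(m_sw$specificity, m$sensitivity)
    }
  }
})

test_that("the pipeline runs end to end on a small image fixture", {
  ds <- make_image_dataset(12, fixture_specs(), size = 32, levels = 32, seed = 2)
  cfg <- run_config(seed = 3,
                    preprocess = preprocess_config(target_size = c(32, 32)),
                    hho = hho_params(n_pop = 6, n_iter = 4),
                    classifier = classifier_config(epochs = 80))
  res <- run_pipeline(ds, cfg)
  expect_s3_class(res, "pipeline_result")
  expect_s3_class(res$report, "classification_report")
  expect_identical(res$report$n, length(res$split$test_idx))
  expect_identical(res$manifest$n_features, 40L)
  expect_gte(res$manifest$n_selected, 1L)
  # metrics recompute exactly from counts
  cc <- res$report$counts
  expect_equal(res$report$accuracy, 100 * (cc$tp + cc$tn) / res$report$n)
})

test_that("the pipeline accepts a precomputed feature table", {
  tab <- make_planted_feature_table(planted_table_spec(80, 12, 3, 3, seed = 6))
  cfg <- run_config(seed = 2,
                    hho = hho_params(n_pop = 6, n_iter = 4),
                    classifier = classifier_config(epochs = 60))
  res <- run_pipeline(tab, cfg)
  expect_identical(res$manifest$n_features, 12L)
  expect_gt(res$report$accuracy, 80)
})

test_that("pipeline artifacts are written and reports are reproducible", {
  ds <- make_image_dataset(8, fixture_specs(), size = 32, levels = 32, seed = 4)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  base <- run_config(seed = 9,
                     preprocess = preprocess_config(target_size = c(32, 32)),
                     hho = hho_params(n_pop = 5, n_iter = 3),
                     classifier = classifier_config(epochs = 50))
  c1 <- base; c1$out_dir <- d1
  c2 <- base; c2$out_dir <- d2
  run_pipeline(ds, c1); run_pipeline(ds, c2)
  for (f in c("report.json", "selected_mask.csv", "history.csv")) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6), label = f)
  }
  rep_json <- jsonlite::read_json(file.path(d1, "report.json"))
  expect_true(all(c("accuracy", "sensitivity", "precision", "specificity",
                    "paper_precision", "counts") %in% names(rep_json)))
})
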