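# toy feature table: one informative column, one noise column
toy_features <- function(n_patients = 20, days = 4, informative = TRUE,
                         seed = 1) {
  set.seed(seed)
  rows <- do.call(rbind, lapply(seq_len(n_patients), function(i) {
    y <- rbinom(days, 1, 0.5)
    data.frame(patient_id = sprintf("P%02d", i),
               day_index = seq_len(days) - 1L, delirium = y)
  }))
  rows$signal <- if (informative) rows$delirium + rnorm(nrow(rows), 0, 0.1)
    else rnorm(nrow(rows))
  rows$noise <- rnorm(nrow(rows))
  tibble::as_tibble(rows)
}

test_that("splits are patient-disjoint, sized by floor, and reproducible", {
  ids <- sprintf("P%02d", 1:10)
  sp <- make_splits(ids, n_boot = 50, train_frac = 0.8, seed = 4)
  expect_length(sp, 50L)
  for (s in sp) {
    expect_length(s$train, 8L)
    expect_length(s$test, 2L)
    expect_length(intersect(s$train, s$test), 0L)
    expect_setequal(c(s$train, s$test), ids)
  }
  expect_identical(sp, make_splits(ids, n_boot = 50, train_frac = 0.8,
                                   seed = 4))
  expect_error(make_splits("P1", 5), "at least 2")
  expect_error(make_splits(ids, 5, train_frac = 1), "train_frac")
})

test_that("a separable problem is learned perfectly on its training data", {
  ft <- toy_features()
  x <- as.matrix(ft[c("signal", "noise")])
  fit <- train_classifier(x, ft$delirium, seed = 3)
  expect_equal(mean((predict(fit, x) >= 0.5) == ft$delirium), 1)
  expect_equal(fit$hyperparams$learning_rate, 0.03)
  expect_equal(fit$hyperparams$max_depth, 5)
  expect_equal(fit$hyperparams$min_child_weight, 1)
  expect_equal(fit$hyperparams$subsample, 0.8)
  expect_equal(fit$hyperparams$colsample, 0.8)
  expect_error(train_classifier(x, rep(1, nrow(x))), "single class")
})

test_that("metrics match their definitions on a hand-built confusion", {
  # TP=2 FP=1 FN=1 TN=6 -> F1 = 2*2/(2*2+1+1) = 2/3
  truth <- c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0)
  prob <- c(0.9, 0.8, 0.1, 0.7, 0.2, 0.2, 0.1, 0.1, 0.2, 0.1)
  m <- evaluate_metrics(truth, prob)
  expect_equal(m$f1, 2 / 3)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$balanced_accuracy, mean(c(2 / 3, 6 / 7)))

  perfect <- evaluate_metrics(c(0, 1, 1), c(0.1, 0.9, 0.8))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$roc_auc, 1)

  flat <- evaluate_metrics(c(0, 1, 0, 1), rep(0.5, 4))
  expect_equal(flat$roc_auc, 0.5)

  one_class <- evaluate_metrics(c(1, 1), c(0.9, 0.2))
  expect_true(is.na(one_class$roc_auc))
  expect_error(evaluate_metrics(numeric(), numeric()), "empty")
})

test_that("hard-label AUC mode ranks by the thresholded class", {
  truth <- c(0, 0, 1, 1)
  prob <- c(0.1, 0.6, 0.7, 0.9)
  m <- evaluate_metrics(truth, prob, auc_mode = "label")
  # sensitivity 1, specificity 0.5 -> trapezoid AUC 0.75 = balanced accuracy
  expect_equal(m$roc_auc, m$balanced_accuracy)
})

test_that("bootstrap evaluation learns signal and stores pairing info", {
  ft <- toy_features(n_patients = 16, days = 4, seed = 5)
  res <- bootstrap_evaluate(ft, n_boot = 12, seed = 6)
  expect_s3_class(res, "bootstrap_result")
  agg <- aggregate_metrics(res)
  expect_gt(agg$mean[agg$metric == "accuracy"], 0.9)
  # aggregation equals a recomputation from the stored per-iteration metrics
  ok <- res$metrics[!res$metrics$degenerate, ]
  expect_equal(agg$mean[agg$metric == "f1"], mean(ok$f1, na.rm = TRUE))
  expect_equal(agg$sd[agg$metric == "roc_auc"], sd(ok$roc_auc, na.rm = TRUE))
})

test_that("ablation rows share identical split plans (paired design)", {
  ft <- toy_features(n_patients = 12, days = 3, seed = 7)
  # treat `signal` as one block and `noise` as another via explicit columns
  coh <- small_cohort(n_patients = 6, days = 2, seed = 7)
  full <- build_feature_table(coh)
  ab <- run_ablation(full, featuresets = default_featuresets()[c(1, 7)],
                     n_boot = 6, seed = 8)
  hashes <- vapply(ab$results, function(r) r$split_hash, "")
  expect_equal(length(unique(hashes)), 1L)
  expect_equal(nrow(ab$table), 2L)
})

test_that("comparing a result with itself gives zero difference, p = 1", {
  ft <- toy_features(n_patients = 12, days = 3, seed = 9)
  res <- bootstrap_evaluate(ft, n_boot = 8, seed = 10)
  cmp <- compare_featuresets(res, res)
  expect_equal(cmp$mean_difference, 0)
  expect_equal(cmp$p_value, 1)
})

test_that("the paired test is two-sided: sign flips leave p unchanged", {
  fake <- function(acc) {
    structure(list(metrics = tibble::tibble(iteration = seq_along(acc),
                                            accuracy = acc,
                                            degenerate = FALSE),
                   split_hash = "h"), class = "bootstrap_result")
  }
  set.seed(11)
  base <- runif(30, 0.5, 0.9)
  d <- rnorm(30, 0.05, 0.03)
  up <- compare_featuresets(fake(base + d), fake(base))
  down <- compare_featuresets(fake(base - d), fake(base))
  expect_equal(up$p_value, down$p_value)
  expect_equal(up$mean_difference, -down$mean_difference)
  expect_error(compare_featuresets(fake(base),
                                   structure(list(metrics = NULL,
                                                  split_hash = "other"),
                                             class = "bootstrap_result")),
               "split plans")
})

test_that("importance ranks the informative feature first, constants at 0", {
  ft <- toy_features(n_patients = 16, days = 4, seed = 12)
  ft$constant <- 1
  res <- bootstrap_evaluate(ft, n_boot = 8, seed = 13)
  imp <- feature_importance(res)
  expect_equal(imp$feature[1], "signal")
  expect_equal(imp$gain[imp$feature == "constant"], 0)

  svm_res <- res
  svm_res$model <- "svm"
  expect_error(feature_importance(svm_res), "tree")
})

test_that("degenerate single-class folds are skipped and counted", {
  ft <- toy_features(n_patients = 6, days = 2, seed = 14)
  ft$delirium <- c(rep(1L, 10), 0L, 1L)  # patient 6 carries the only 0 day
  res <- bootstrap_evaluate(ft, n_boot = 20, seed = 15)
  expect_gt(res$n_degenerate, 0)
  expect_true(all(is.na(res$metrics$accuracy[res$metrics$degenerate])))
  agg <- aggregate_metrics(res)
  expect_equal(unique(agg$n[agg$metric == "accuracy"]),
               nrow(res$metrics) - res$n_degenerate)
})

test_that("alternative classifiers run behind the same interface", {
  skip_if_not_installed("randomForest")
  skip_if_not_installed("e1071")
  ft <- toy_features(n_patients = 10, days = 3, seed = 16)
  x <- as.matrix(ft[c("signal", "noise")])
  for (m in c("random_forest", "svm")) {
    fit <- train_classifier(x, ft$delirium, model = m, seed = 17)
    p <- predict(fit, x)
    expect_true(all(p >= 0 & p <= 1))
    expect_gt(mean((p >= 0.5) == ft$delirium), 0.9)
  }
})
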