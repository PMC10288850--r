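#' Default gradient-boosting hyperparameters
#'
#' Learning rate 0.03, maximum tree depth 5, minimum child weight 1,
#' subsample fraction 0.8, column fraction 0.8. The ensemble size
#' (`n_estimators = 200`) is a package default.
#'
#' @return A named list.
#' @export
default_hyperparams <- function() {
  list(learning_rate = 0.03, max_depth = 5, min_child_weight = 1,
       subsample = 0.8, colsample = 0.8, n_estimators = 200L)
}

#' Generate patient-disjoint bootstrap split plans
#'
#' Each iteration draws `floor(train_frac * n)` patients (without
#' replacement) for training and leaves the rest for testing, so no
#' patient's days ever appear on both sides. Iteration `k` is seeded with
#' `seed + k`, making any single iteration reproducible in isolation.
#'
#' @param patient_ids character vector of distinct patient ids.
#' @param n_boot number of iterations.
#' @param train_frac fraction of patients in the training side, in (0, 1).
#' @param seed root integer seed.
#' @return A list of `n_boot` plans, each
#'   `list(iteration, train, test, seed)`.
#' @export
make_splits <- function(patient_ids, n_boot = 500L, train_frac = 0.8,
                        seed = 1L) {
  patient_ids <- unique(patient_ids)
  n <- length(patient_ids)
  if (n < 2L) stop("need at least 2 patients to split", call. = FALSE)
  if (train_frac <= 0 || train_frac >= 1) {
    stop("train_frac must be strictly between 0 and 1", call. = FALSE)
  }
  n_train <- floor(train_frac * n)
  n_train <- min(max(n_train, 1L), n - 1L)  # at least one patient per side
  lapply(seq_len(n_boot), function(k) {
    it_seed <- as.integer(seed) + k
    set.seed(it_seed)
    train <- sort(sample(patient_ids, n_train))
    list(iteration = k, train = train,
         test = sort(setdiff(patient_ids, train)), seed = it_seed)
  })
}

#' Train a day-level delirium classifier
#'
#' @param x numeric feature matrix (rows = patient-days). `NA` entries are
#'   handled natively by gradient boosting; for the alternatives they are
#'   median-imputed from the training columns.
#' @param y 0/1 outcome vector (1 = delirium day).
#' @param model `"xgboost"` (default), `"random_forest"` or `"svm"`.
#' @param hyperparams list as from [default_hyperparams()] (used by the
#'   xgboost model).
#' @param seed integer seed for the stochastic parts of training.
#' @return An object of class `"actidel_model"` usable with `predict()`
#'   (returns probabilities of the delirium class).
#' @export
train_classifier <- function(x, y,
                             model = c("xgboost", "random_forest", "svm"),
                             hyperparams = default_hyperparams(),
                             seed = 1L) {
  model <- match.arg(model)
  if (length(unique(y[!is.na(y)])) < 2L) {
    stop("training labels contain a single class", call. = FALSE)
  }
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  set.seed(seed)
  fit <- switch(model,
    xgboost = {
      dtrain <- xgboost::xgb.DMatrix(x, label = y)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      eta = hyperparams$learning_rate,
                      max_depth = hyperparams$max_depth,
                      min_child_weight = hyperparams$min_child_weight,
                      subsample = hyperparams$subsample,
                      colsample_bytree = hyperparams$colsample,
                      nthread = 1L, seed = seed),
        data = dtrain, nrounds = hyperparams$n_estimators, verbose = 0)
    },
    random_forest = {
      if (!requireNamespace("randomForest", quietly = TRUE)) {
        stop("the random_forest model requires the randomForest package",
             call. = FALSE)
      }
      randomForest::randomForest(.impute_median(x), factor(y, levels = 0:1))
    },
    svm = {
      if (!requireNamespace("e1071", quietly = TRUE)) {
        stop("the svm model requires the e1071 package", call. = FALSE)
      }
      e1071::svm(.impute_median(x), factor(y, levels = 0:1),
                 probability = TRUE)
    })
  structure(list(fit = fit, model = model,
                 feature_names = colnames(x),
                 medians = apply(x, 2L, stats::median, na.rm = TRUE),
                 hyperparams = hyperparams),
            class = "actidel_model")
}

.impute_median <- function(x, medians = NULL) {
  if (is.null(medians)) medians <- apply(x, 2L, stats::median, na.rm = TRUE)
  medians[is.na(medians)] <- 0
  for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- medians[j]
  x
}

#' @export
predict.actidel_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  storage.mode(x) <- "double"
  switch(object$model,
    xgboost = predict(object$fit, xgboost::xgb.DMatrix(x)),
    random_forest = predict(object$fit,
                            .impute_median(x, object$medians),
                            type = "prob")[, "1"],
    svm = {
      p <- predict(object$fit, .impute_median(x, object$medians),
                   probability = TRUE)
      attr(p, "probabilities")[, "1"]
    })
}

#' Classification metrics for one test fold
#'
#' Accuracy, balanced accuracy (mean per-class recall over the classes
#' present in the truth), F1 with delirium as positive class, and ROC-AUC.
#' With a single-class test fold the ROC-AUC is undefined and reported
#' `NA`; the other metrics are still computed.
#'
#' @param truth 0/1 vector.
#' @param prob predicted delirium probabilities.
#' @param threshold classification cut-off for the label-based metrics.
#' @param auc_mode `"prob"` ranks by probability; `"label"` ranks by the
#'   thresholded class instead.
#' @return Named list with `accuracy`, `balanced_accuracy`, `f1`,
#'   `roc_auc`.
#' @export
evaluate_metrics <- function(truth, prob, threshold = 0.5,
                             auc_mode = c("prob", "label")) {
  auc_mode <- match.arg(auc_mode)
  if (length(truth) == 0L) stop("empty test set", call. = FALSE)
  pred <- as.integer(prob >= threshold)
  acc <- mean(pred == truth)
  recalls <- vapply(intersect(0:1, truth),
                    function(cl) mean(pred[truth == cl] == cl), 0)
  bacc <- mean(recalls)
  tp <- sum(pred == 1L & truth == 1L)
  fp <- sum(pred == 1L & truth == 0L)
  fn <- sum(pred == 0L & truth == 1L)
  f1 <- if (2 * tp + fp + fn == 0) NA_real_ else 2 * tp / (2 * tp + fp + fn)
  auc <- if (length(unique(truth)) < 2L) NA_real_ else {
    predictor <- if (auc_mode == "prob") prob else as.numeric(pred)
    if (length(unique(predictor)) < 2L) 0.5 else
      as.numeric(pROC::auc(pROC::roc(truth, predictor, quiet = TRUE,
                                     levels = c(0, 1), direction = "<")))
  }
  list(accuracy = acc, balanced_accuracy = bacc, f1 = f1, roc_auc = auc)
}

#' Patient-disjoint bootstrap evaluation of a feature table
#'
#' Repeats, over `n_boot` random patient-disjoint 80/20 splits, the cycle
#' train -> predict held-out patients' days -> score. Iterations whose
#' training fold contains a single class are marked degenerate, skipped
#' and counted. Per-iteration feature importances (fraction of total
#' information gain) are stored for [feature_importance()].
#'
#' @param features a day-level feature table from [build_feature_table()]
#'   (or any tibble with `patient_id`, `delirium` and numeric feature
#'   columns).
#' @param n_boot number of bootstrap iterations.
#' @param train_frac training fraction of patients.
#' @param model,hyperparams passed to [train_classifier()].
#' @param seed root seed; ignored for splitting when `splits` is given.
#' @param splits optional pre-made [make_splits()] plans, for paired
#'   comparisons across feature sets.
#' @param auc_mode see [evaluate_metrics()].
#' @return An object of class `"bootstrap_result"`: per-iteration
#'   `metrics` tibble, importance matrix, the split plans and their hash,
#'   the degenerate-iteration count, and the model configuration.
#' @export
bootstrap_evaluate <- function(features, n_boot = 500L, train_frac = 0.8,
                               model = "xgboost",
                               hyperparams = default_hyperparams(),
                               seed = 1L, splits = NULL,
                               auc_mode = "prob") {
  feature_cols <- attr(features, "feature_cols")
  if (is.null(feature_cols)) {
    feature_cols <- setdiff(names(features),
                            c("patient_id", "day_index", "delirium"))
  }
  if (length(feature_cols) == 0L) stop("no feature columns", call. = FALSE)
  if (is.null(splits)) {
    splits <- make_splits(unique(features$patient_id), n_boot, train_frac,
                          seed)
  }
  x <- as.matrix(features[feature_cols])
  storage.mode(x) <- "double"
  y <- features$delirium
  pid <- features$patient_id

  gain <- matrix(NA_real_, length(splits), length(feature_cols),
                 dimnames = list(NULL, feature_cols))
  rows <- vector("list", length(splits))
  for (k in seq_along(splits)) {
    sp <- splits[[k]]
    tr <- pid %in% sp$train
    te <- pid %in% sp$test
    degenerate <- length(unique(y[tr])) < 2L || !any(te)
    if (degenerate) {
      rows[[k]] <- tibble::tibble(iteration = sp$iteration,
                                  accuracy = NA_real_,
                                  balanced_accuracy = NA_real_,
                                  f1 = NA_real_, roc_auc = NA_real_,
                                  degenerate = TRUE)
      next
    }
    fit <- train_classifier(x[tr, , drop = FALSE], y[tr], model = model,
                            hyperparams = hyperparams, seed = sp$seed)
    m <- evaluate_metrics(y[te], predict(fit, x[te, , drop = FALSE]),
                          auc_mode = auc_mode)
    gain[k, ] <- .model_gain(fit, feature_cols)
    rows[[k]] <- tibble::tibble(iteration = sp$iteration,
                                accuracy = m$accuracy,
                                balanced_accuracy = m$balanced_accuracy,
                                f1 = m$f1, roc_auc = m$roc_auc,
                                degenerate = FALSE)
  }
  metrics <- dplyr::bind_rows(rows)
  structure(list(metrics = metrics, gain = gain, splits = splits,
                 split_hash = rlang::hash(lapply(splits, function(s)
                   s[c("train", "test")])),
                 n_degenerate = sum(metrics$degenerate),
                 model = model, hyperparams = hyperparams,
                 feature_cols = feature_cols),
            class = "bootstrap_result")
}

# per-model importance: fraction of total information gain per feature
.model_gain <- function(fit, feature_cols) {
  g <- setNames(rep(0, length(feature_cols)), feature_cols)
  if (fit$model == "xgboost") {
    imp <- xgboost::xgb.importance(model = fit$fit)
    g[imp$Feature] <- imp$Gain
  } else if (fit$model == "random_forest") {
    imp <- fit$fit$importance[, "MeanDecreaseGini"]
    if (sum(imp) > 0) imp <- imp / sum(imp)
    g[names(imp)] <- imp
  } else {
    g[] <- NA_real_
  }
  g
}

#' @export
print.bootstrap_result <- function(x, ...) {
  agg <- aggregate_metrics(x)
  cat(sprintf("<bootstrap_result> %s, %d iterations (%d degenerate)\n",
              x$model, nrow(x$metrics), x$n_degenerate))
  for (i in seq_len(nrow(agg))) {
    cat(sprintf("  %-18s %.3f +/- %.3f\n", agg$metric[i], agg$mean[i],
                agg$sd[i]))
  }
  invisible(x)
}

#' Aggregate per-iteration metrics
#'
#' Arithmetic mean and SD over the iterations in which each metric is
#' defined (degenerate iterations excluded).
#'
#' @param result a `bootstrap_result`.
#' @return A tibble with columns `metric`, `mean`, `sd`, `n`.
#' @export
aggregate_metrics <- function(result) {
  m <- result$metrics[!result$metrics$degenerate, ]
  dplyr::bind_rows(lapply(c("accuracy", "balanced_accuracy", "f1",
                            "roc_auc"), function(col) {
    v <- m[[col]][!is.na(m[[col]])]
    tibble::tibble(metric = col, mean = mean(v), sd = stats::sd(v),
                   n = length(v))
  }))
}

#' The seven canonical feature-set configurations
#'
#' Clinical covariates alone and in combination with minutes at rest and
#' the two DTW control schemes, in the standard reporting order.
#'
#' @return A named list mapping configuration label to feature blocks.
#' @export
default_featuresets <- function() {
  list(
    "Clinical only" = "clinical",
    "Clinical + minutes at rest" = c("clinical", "minutes_at_rest"),
    "Clinical + non-paretic arm DTW" = c("clinical", "non_paretic_arm_dtw"),
    "Clinical + non-paretic arm DTW + minutes at rest" =
      c("clinical", "non_paretic_arm_dtw", "minutes_at_rest"),
    "Clinical + reference day DTW" = c("clinical", "reference_day_dtw"),
    "Clinical + reference day DTW + minutes at rest" =
      c("clinical", "reference_day_dtw", "minutes_at_rest"),
    "Clinical + non-paretic arm DTW + reference day DTW + minutes at rest" =
      c("clinical", "non_paretic_arm_dtw", "reference_day_dtw",
        "minutes_at_rest")
  )
}

.BLOCK_PATTERNS <- c(clinical = "^(ventilated|age|sex|nihss|ich_volume_cc|lobar|deep|ivh|ich_score)$",
                     minutes_at_rest = "^rest_",
                     non_paretic_arm_dtw = "^dtw_nonparetic_",
                     reference_day_dtw = "^dtw_refday_")

.block_columns <- function(features, blocks) {
  cols <- character()
  for (b in blocks) {
    cols <- c(cols, grep(.BLOCK_PATTERNS[[b]], names(features),
                         value = TRUE))
  }
  cols
}

#' Feature-set ablation over shared bootstrap splits
#'
#' Evaluates each feature-set configuration with identical split plans, so
#' that per-iteration metrics are paired across configurations and
#' [compare_featuresets()] can test differences.
#'
#' @param features a feature table built with all feature blocks
#'   ([build_feature_table()] defaults).
#' @param featuresets named list mapping row label to feature blocks;
#'   default [default_featuresets()].
#' @param n_boot,train_frac,model,hyperparams,seed,auc_mode passed through
#'   to [bootstrap_evaluate()].
#' @return An object of class `"ablation_result"`: `table` (one row per
#'   configuration with mean +/- SD of each metric) and `results` (the
#'   underlying `bootstrap_result`s, sharing split plans).
#' @export
run_ablation <- function(features, featuresets = default_featuresets(),
                         n_boot = 500L, train_frac = 0.8,
                         model = "xgboost",
                         hyperparams = default_hyperparams(), seed = 1L,
                         auc_mode = "prob") {
  splits <- make_splits(unique(features$patient_id), n_boot, train_frac,
                        seed)
  results <- list()
  rows <- list()
  for (label in names(featuresets)) {
    cols <- .block_columns(features, featuresets[[label]])
    if (length(cols) == 0L) {
      stop(sprintf("feature table has no columns for configuration '%s'",
                   label), call. = FALSE)
    }
    sub <- features
    attr(sub, "feature_cols") <- cols
    res <- bootstrap_evaluate(sub, model = model,
                              hyperparams = hyperparams, seed = seed,
                              splits = splits, auc_mode = auc_mode)
    results[[label]] <- res
    agg <- aggregate_metrics(res)
    row <- tibble::tibble(featureset = label)
    for (i in seq_len(nrow(agg))) {
      row[[paste0(agg$metric[i], "_mean")]] <- agg$mean[i]
      row[[paste0(agg$metric[i], "_sd")]] <- agg$sd[i]
    }
    row$n_iterations <- nrow(res$metrics) - res$n_degenerate
    rows[[label]] <- row
  }
  structure(list(table = dplyr::bind_rows(rows), results = results),
            class = "ablation_result")
}

#' @export
print.ablation_result <- function(x, ...) {
  cat("<ablation_result>\n")
  t <- x$table
  for (i in seq_len(nrow(t))) {
    cat(sprintf("  %-70s acc %.2f+/-%.2f  f1 %.2f+/-%.2f\n",
                t$featureset[i], t$accuracy_mean[i], t$accuracy_sd[i],
                t$f1_mean[i], t$f1_sd[i]))
  }
  invisible(x)
}

#' Paired comparison of two feature-set configurations
#'
#' Two-sided paired test on per-iteration metric differences. The two
#' results must come from the same split plans (checked by hash), so the
#' comparison is paired iteration by iteration. Because bootstrap
#' iterations reuse patients, they are not independent samples; p-values
#' are descriptive.
#'
#' @param result_a,result_b `bootstrap_result`s sharing split plans.
#' @param metric which per-iteration metric to compare.
#' @param test `"t"` (paired t-test) or `"wilcoxon"` (signed rank).
#' @return `list(metric, test, mean_difference, p_value, n_pairs)`;
#'   `p_value` is 1 when the paired differences are identically zero.
#' @export
compare_featuresets <- function(result_a, result_b, metric = "accuracy",
                                test = c("t", "wilcoxon")) {
  test <- match.arg(test)
  if (!identical(result_a$split_hash, result_b$split_hash)) {
    stop("results were not computed on identical split plans", call. = FALSE)
  }
  a <- result_a$metrics[[metric]]
  b <- result_b$metrics[[metric]]
  ok <- !is.na(a) & !is.na(b)
  d <- a[ok] - b[ok]
  if (length(d) < 2L) stop("too few paired iterations", call. = FALSE)
  p <- if (all(d == 0)) 1 else if (test == "t") {
    stats::t.test(d)$p.value
  } else {
    stats::wilcox.test(d, exact = FALSE)$p.value
  }
  list(metric = metric, test = test, mean_difference = mean(d),
       p_value = p, n_pairs = length(d))
}

#' Mean information-gain feature importance
#'
#' Per-feature importance (fraction of the ensemble's total information
#' gain) averaged over non-degenerate bootstrap iterations; features a
#' model never splits on contribute 0. Only tree-ensemble models carry
#' gain; results from an SVM raise an error.
#'
#' @param result a `bootstrap_result`.
#' @return A tibble `feature`, `gain`, sorted by decreasing gain.
#' @export
feature_importance <- function(result) {
  if (!result$model %in% c("xgboost", "random_forest")) {
    stop("information-gain importance requires a tree-ensemble model",
         call. = FALSE)
  }
  g <- result$gain[!result$metrics$degenerate, , drop = FALSE]
  if (nrow(g) == 0L) stop("no fitted iterations", call. = FALSE)
  out <- tibble::tibble(feature = colnames(g), gain = unname(colMeans(g)))
  dplyr::arrange(out, dplyr::desc(.data$gain))
}
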