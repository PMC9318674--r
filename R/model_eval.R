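# Random-forest depressed-mood classification protocol and metrics.
#
# A single random 3:1 train/test split (test size = ceil(n/4)); a random
# forest of 1000 trees with maximum depth 100; per-class precision/recall/F1
# plus accuracy, with macro and support-weighted aggregates both reported
# (aggregation mode always labelled); per-feature-group ablation; and a
# comparison of test-set predictions against clinician diagnosis.

POSITIVE_CLASS <- "DEPRESSED"
NEGATIVE_CLASS <- "NON_DEPRESSED"

#' Model configuration
#'
#' @param n_trees number of trees (default 1000).
#' @param max_tree_depth maximum tree depth (default 100).
#' @param seed integer RNG seed (required: the split and the forest are
#'   seeded explicitly so every report is reproducible).
#' @param label_source which questionnaire defines the training label:
#'   `"PHQ9"` or `"CESDR"`.
#' @return a `model_config` list.
#' @export
modelConfig <- function(n_trees = 1000L, max_tree_depth = 100L, seed,
                        label_source = c("PHQ9", "CESDR")) {
  stopifnot(n_trees >= 1L, max_tree_depth >= 1L)
  structure(list(n_trees = as.integer(n_trees),
                 max_tree_depth = as.integer(max_tree_depth),
                 seed = as.integer(seed),
                 label_source = match.arg(label_source)),
            class = "model_config")
}

#' Random 3:1 train/test split
#'
#' @param ids vector of participant ids (n >= 4).
#' @param test_fraction fraction assigned to the test set; the test size is
#'   `ceiling(n * test_fraction)` (default 0.25, i.e. 106 -> 79/27).
#' @param seed integer seed; the same seed reproduces the same partition.
#' @return list with `train_ids`, `test_ids`, `seed`.
#' @export
splitCohort <- function(ids, test_fraction = 0.25, seed) {
  n <- length(ids)
  if (n < 4L) stop("splitCohort: need at least 4 ids", call. = FALSE)
  stopifnot(test_fraction > 0, test_fraction < 1)
  n_test <- as.integer(ceiling(n * test_fraction))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  test <- sort(sample.int(n, n_test))
  list(train_ids = ids[-test], test_ids = ids[test], seed = as.integer(seed))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Train the depressed-mood random forest
#'
#' An ensemble of depth-bounded classification trees; feature importances
#' (impurity decrease) are retained so the derived-feature design stays
#' interpretable. Under the `"impute"` missing policy, NA entries are filled
#' with training-set column means (stored in the model for test-time use).
#'
#' @param features numeric matrix or data.frame (rows = participants, 33
#'   feature columns).
#' @param labels character/factor vector: `"DEPRESSED"` / `"NON_DEPRESSED"`.
#' @param config a [modelConfig()].
#' @return a `mood_model`: list with the fitted forest, the config, training
#'   column means and feature names.
#' @export
trainModel <- function(features, labels, config) {
  stopifnot(inherits(config, "model_config"))
  x <- as.data.frame(features)
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels))
  if (length(unique(labels)) < 2L) {
    stop("trainModel: training labels contain a single class", call. = FALSE)
  }
  col_means <- vapply(x, function(cc) mean(cc, na.rm = TRUE), numeric(1))
  for (cc in names(x)) x[[cc]][is.na(x[[cc]])] <- col_means[[cc]]
  y <- factor(labels, levels = c(NEGATIVE_CLASS, POSITIVE_CLASS))
  fit <- ranger::ranger(x = x, y = y,
                        num.trees = config$n_trees,
                        max.depth = config$max_tree_depth,
                        importance = "impurity",
                        seed = config$seed,
                        num.threads = 1L)
  structure(list(forest = fit, config = config, col_means = col_means,
                 feature_names = names(x)),
            class = "mood_model")
}

#' Predict depressed-mood labels
#'
#' Majority vote of the forest (0.5 threshold).
#'
#' @param object a `mood_model`.
#' @param newdata feature matrix/data.frame with the training columns.
#' @param ... unused.
#' @return character vector of `"DEPRESSED"` / `"NON_DEPRESSED"`.
#' @export
predict.mood_model <- function(object, newdata, ...) {
  x <- as.data.frame(newdata)[, object$feature_names, drop = FALSE]
  for (cc in names(x)) x[[cc]][is.na(x[[cc]])] <- object$col_means[[cc]]
  as.character(predict(object$forest, data = x,
                       num.threads = 1L)$predictions)
}

#' Feature importances of a fitted model
#' @param model a `mood_model`.
#' @return named numeric vector (impurity-decrease importance).
#' @export
featureImportance <- function(model) {
  ranger::importance(model$forest)
}

#' Evaluation report: per-class and aggregate precision/recall/F1
#'
#' Precision = TP/(TP+FP), recall = TP/(TP+FN), F1 = their harmonic mean, per
#' class; accuracy = (TP+TN)/n. Aggregates are reported both macro-averaged
#' and support-weighted, with the mode labelled — never as an unlabelled
#' "total". All metrics are percentages. A class with zero predicted
#' positives has undefined precision, reported as NA (not 0).
#'
#' @param predictions character vector of predicted labels.
#' @param truth character vector of true labels (same length).
#' @param positive label treated as the positive class (default
#'   `"DEPRESSED"`).
#' @return an `eval_report`: list with `per_class` (data.frame class,
#'   precision, recall, f1, support), `accuracy`, `aggregate` (data.frame
#'   mode, precision, recall, f1) and `confusion` (2x2 table).
#' @export
evaluatePredictions <- function(predictions, truth,
                                positive = POSITIVE_CLASS) {
  stopifnot(length(predictions) == length(truth))
  predictions <- as.character(predictions)
  truth <- as.character(truth)
  classes <- c(positive, setdiff(unique(c(truth, predictions)), positive))
  n <- length(truth)
  per <- lapply(classes, function(cl) {
    tp <- sum(predictions == cl & truth == cl)
    fp <- sum(predictions == cl & truth != cl)
    fn <- sum(predictions != cl & truth == cl)
    prec <- if (tp + fp == 0L) NA_real_ else 100 * tp / (tp + fp)
    rec <- if (tp + fn == 0L) NA_real_ else 100 * tp / (tp + fn)
    f1 <- if (is.na(prec) || is.na(rec) || prec + rec == 0) NA_real_ else
      2 * prec * rec / (prec + rec)
    data.frame(class = cl, precision = prec, recall = rec, f1 = f1,
               support = sum(truth == cl), stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  w <- per$support / sum(per$support)
  agg <- rbind(
    data.frame(mode = "macro", precision = mean(per$precision),
               recall = mean(per$recall), f1 = mean(per$f1)),
    data.frame(mode = "weighted", precision = sum(w * per$precision),
               recall = sum(w * per$recall), f1 = sum(w * per$f1)))
  confusion <- table(truth = factor(truth, levels = classes),
                     predicted = factor(predictions, levels = classes))
  structure(list(per_class = per,
                 accuracy = 100 * mean(predictions == truth),
                 aggregate = agg, confusion = confusion, n = n),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> n =", x$n, " accuracy =",
      sprintf("%.2f%%", x$accuracy), "\n")
  pc <- x$per_class
  pc[, 2:4] <- round(pc[, 2:4], 2)
  print(pc, row.names = FALSE)
  ag <- x$aggregate
  ag[, 2:4] <- round(ag[, 2:4], 2)
  cat("aggregates (mode labelled):\n")
  print(ag, row.names = FALSE)
  invisible(x)
}

#' F1 score from precision and recall (percent)
#'
#' Harmonic mean: `2 P R / (P + R)`.
#'
#' @param precision,recall percentages.
#' @return F1 as a percentage.
#' @export
f1Score <- function(precision, recall) {
  2 * precision * recall / (precision + recall)
}

#' Per-feature-group ablation
#'
#' Trains one forest per feature group restricted to that group's columns,
#' plus the all-features model, and reports the test-set accuracy of each on
#' the common split — the per-group contribution comparison.
#'
#' @param features feature data.frame with `participant_id` and the 33
#'   feature columns.
#' @param labels named character vector of labels (names = participant ids).
#' @param split a [splitCohort()] result.
#' @param config a [modelConfig()].
#' @param groups named list of column-index vectors into [featureNames()];
#'   the default merges mobility and activity into one physical-activity
#'   block, alongside sleep, expression and all.
#' @return named numeric of test accuracies (percent), one per group plus
#'   `"all"`.
#' @export
ablationByGroup <- function(features, labels, split, config,
                            groups = list(
                              sleep = FEATURE_GROUPS$sleep,
                              activity = c(FEATURE_GROUPS$mobility,
                                           FEATURE_GROUPS$activity),
                              expression = FEATURE_GROUPS$expression,
                              all = seq_along(featureNames()))) {
  if (any(lengths(groups) == 0L)) {
    stop("ablationByGroup: empty feature group", call. = FALSE)
  }
  fmat <- features[, featureNames(), drop = FALSE]
  rownames(fmat) <- features$participant_id
  vapply(groups, function(idx) {
    xt <- fmat[split$train_ids, idx, drop = FALSE]
    xs <- fmat[split$test_ids, idx, drop = FALSE]
    model <- trainModel(xt, labels[split$train_ids], config)
    pred <- predict(model, xs)
    100 * mean(pred == labels[split$test_ids])
  }, numeric(1))
}

#' Compare predictions with clinician diagnosis
#'
#' Evaluates test-set predictions against the clinician's
#' depressive/non-depressive diagnosis instead of the questionnaire label,
#' and also returns the depressed-class row on its own (how many diagnosed
#' depressive participants the system recovered).
#'
#' @param predictions named character vector (`"DEPRESSED"` /
#'   `"NON_DEPRESSED"`), names = participant ids.
#' @param diagnosis named character vector (`"DEPRESSIVE"` /
#'   `"NON_DEPRESSIVE"`); participants with missing diagnosis are excluded
#'   (count reported).
#' @return list: `report` (an `eval_report`), `depressed_row` (the positive
#'   class metrics), `n_excluded`.
#' @export
compareToDiagnosis <- function(predictions, diagnosis) {
  ids <- names(predictions)
  stopifnot(!is.null(ids))
  diag <- diagnosis[ids]
  keep <- !is.na(diag)
  truth <- ifelse(diag[keep] == "DEPRESSIVE", POSITIVE_CLASS, NEGATIVE_CLASS)
  rep <- evaluatePredictions(predictions[keep], truth)
  list(report = rep,
       depressed_row = rep$per_class[rep$per_class$class == POSITIVE_CLASS, ],
       n_excluded = sum(!keep))
}
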