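# End-to-end orchestration: simulate or load a cohort, validate and exclude,
# extract the 33 features, label, split 3:1, train, evaluate against the
# questionnaire label and against clinician diagnosis, ablate by feature
# group, and write a self-describing run directory.

#' Run configuration
#'
#' Exactly one of `input_dir` (a cohort directory with `manifest.csv`) or
#' `simulation_spec` (a [cohortSpec()]) must be supplied.
#'
#' @param input_dir cohort directory to read, or NULL.
#' @param simulation_spec a [cohortSpec()], or NULL.
#' @param label_source `"PHQ9"` or `"CESDR"` — which questionnaire defines
#'   the training label.
#' @param seed integer seed driving the split and the forest.
#' @param feature_config a [featureConfig()].
#' @param n_trees,max_tree_depth forest hyperparameters (defaults 1000, 100).
#' @param exclusion_policy an [exclusionPolicy()].
#' @param output_dir where to write run artifacts, or NULL to skip writing.
#' @return a `run_config` list.
#' @export
runConfig <- function(input_dir = NULL, simulation_spec = NULL,
                      label_source = c("PHQ9", "CESDR"), seed = 1L,
                      feature_config = featureConfig(),
                      n_trees = 1000L, max_tree_depth = 100L,
                      exclusion_policy = exclusionPolicy(),
                      output_dir = NULL) {
  if (is.null(input_dir) == is.null(simulation_spec)) {
    stop("runConfig: supply exactly one of input_dir / simulation_spec",
         call. = FALSE)
  }
  structure(list(input_dir = input_dir, simulation_spec = simulation_spec,
                 label_source = match.arg(label_source),
                 seed = as.integer(seed), feature_config = feature_config,
                 n_trees = as.integer(n_trees),
                 max_tree_depth = as.integer(max_tree_depth),
                 exclusion_policy = exclusion_policy,
                 output_dir = output_dir),
            class = "run_config")
}

#' Run the full pipeline
#'
#' Stages: load/simulate -> exclusion rules -> feature extraction ->
#' questionnaire labels -> 3:1 split -> random forest -> evaluation against
#' the questionnaire label, per-group ablation, and comparison with clinician
#' diagnosis where available. When `output_dir` is set, writes
#' `features.csv`, `report.json`, `report.txt` and `manifest.json` (config
#' hash, seed, per-stage record counts), so a run directory is
#' self-describing and reproducible.
#'
#' @param config a [runConfig()].
#' @return list: `features`, `labels`, `split`, `model`, `eval_label`
#'   (eval_report vs questionnaire label), `ablation` (named accuracies),
#'   `eval_diagnosis` ([compareToDiagnosis()] output or NULL), `exclusion`
#'   (exclusion report), `manifest`.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$simulation_spec)) {
    sim <- generateCohort(config$simulation_spec)
    bundles <- sim$bundles
  } else {
    bundles <- readCohort(config$input_dir)
  }
  excl <- applyExclusionRules(bundles, config$exclusion_policy)
  if (length(excl$retained) < 4L) {
    stop("runPipeline: fewer than 4 participants after exclusion",
         call. = FALSE)
  }
  features <- extractFeatures(excl$retained, config$feature_config)
  kept_ids <- features$participant_id
  labels_df <- labelCohort(excl$retained)
  labels_df <- labels_df[match(kept_ids, labels_df$participant_id), ]
  lab_col <- if (config$label_source == "PHQ9") "phq9_label" else "cesdr_label"
  labels <- setNames(labels_df[[lab_col]], kept_ids)
  if (anyNA(labels)) {
    drop <- names(labels)[is.na(labels)]
    features <- features[!features$participant_id %in% drop, , drop = FALSE]
    labels <- labels[!is.na(labels)]
    kept_ids <- features$participant_id
  }
  mc <- modelConfig(n_trees = config$n_trees,
                    max_tree_depth = config$max_tree_depth,
                    seed = config$seed, label_source = config$label_source)
  split <- splitCohort(kept_ids, seed = config$seed)
  fmat <- features[, featureNames(), drop = FALSE]
  rownames(fmat) <- kept_ids
  model <- trainModel(fmat[split$train_ids, , drop = FALSE],
                      labels[split$train_ids], mc)
  pred <- predict(model, fmat[split$test_ids, , drop = FALSE])
  names(pred) <- split$test_ids
  eval_label <- evaluatePredictions(pred, labels[split$test_ids])
  ablation <- ablationByGroup(features, labels, split, mc)
  diagnosis <- setNames(labels_df$diagnosis, labels_df$participant_id)
  eval_diag <- if (all(is.na(diagnosis[split$test_ids]))) NULL else
    compareToDiagnosis(pred, diagnosis)
  manifest <- list(
    seed = config$seed, label_source = config$label_source,
    n_input = length(bundles), n_retained = length(excl$retained),
    n_features_rows = nrow(features), n_train = length(split$train_ids),
    n_test = length(split$test_ids), n_feature_columns = length(featureNames()),
    config_hash = anonymizeId(paste(deparse(config[c(
      "label_source", "seed", "n_trees", "max_tree_depth")]),
      collapse = ""), salt = "run-config"))
  out <- list(features = features, labels = labels, split = split,
              model = model, predictions = pred, eval_label = eval_label,
              ablation = ablation, eval_diagnosis = eval_diag,
              exclusion = excl$report, manifest = manifest)
  if (!is.null(config$output_dir)) writeRunArtifacts(out, config$output_dir)
  invisible(out)
}

reportAsList <- function(report) {
  list(accuracy = report$accuracy, per_class = report$per_class,
       aggregate = report$aggregate,
       confusion = as.data.frame(report$confusion))
}

writeRunArtifacts <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(run$features, file.path(dir, "features.csv"), row.names = FALSE)
  rep_json <- list(eval_label = reportAsList(run$eval_label),
                   ablation = as.list(run$ablation))
  if (!is.null(run$eval_diagnosis)) {
    rep_json$eval_diagnosis <- reportAsList(run$eval_diagnosis$report)
    rep_json$depressed_row <- run$eval_diagnosis$depressed_row
  }
  jsonlite::write_json(rep_json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(renderReport(run), file.path(dir, "report.txt"))
  invisible(dir)
}

fmtNum <- function(x) ifelse(is.na(x), "NA", sprintf("%.2f", x))

#' Render a text report
#'
#' Two tables: accuracy by derived-feature group (ablation), and
#' precision/recall/F1 per class against the questionnaire label and — when
#' available — against clinician diagnosis, with aggregate rows labelled by
#' aggregation mode.
#'
#' @param run a [runPipeline()] result (or a list with the same fields).
#' @return character vector of report lines.
#' @export
renderReport <- function(run) {
  lines <- character(0)
  push <- function(...) lines <<- c(lines, sprintf(...))
  if (!is.null(run$ablation) && length(run$ablation)) {
    push("Accuracy by derived-feature group (%%)")
    for (g in names(run$ablation)) push("  %-12s %s", g,
                                        fmtNum(run$ablation[[g]]))
    push("")
  }
  renderEval <- function(title, report) {
    push("%s (n = %d, accuracy = %s%%)", title, report$n,
         fmtNum(report$accuracy))
    push("  %-16s %10s %10s %10s %8s", "class", "precision", "recall", "f1",
         "support")
    for (i in seq_len(nrow(report$per_class))) {
      r <- report$per_class[i, ]
      push("  %-16s %10s %10s %10s %8d", r$class, fmtNum(r$precision),
           fmtNum(r$recall), fmtNum(r$f1), r$support)
    }
    for (i in seq_len(nrow(report$aggregate))) {
      a <- report$aggregate[i, ]
      push("  %-16s %10s %10s %10s", paste0("[", a$mode, "]"),
           fmtNum(a$precision), fmtNum(a$recall), fmtNum(a$f1))
    }
    push("")
  }
  renderEval("Prediction vs questionnaire label", run$eval_label)
  if (!is.null(run$eval_diagnosis)) {
    renderEval("Prediction vs clinician diagnosis", run$eval_diagnosis$report)
  }
  lines
}
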