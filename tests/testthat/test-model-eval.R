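test_that("the 3:1 split uses ceiling rounding and is seed-reproducible", {
  ids <- sprintf("p%03d", 1:106)
  sp <- splitCohort(ids, seed = 4)
  expect_length(sp$train_ids, 79L)
  expect_length(sp$test_ids, 27L)
  expect_length(intersect(sp$train_ids, sp$test_ids), 0L)
  expect_setequal(c(sp$train_ids, sp$test_ids), ids)
  sp8 <- splitCohort(letters[1:8], seed = 4)
  expect_length(sp8$train_ids, 6L)
  expect_length(sp8$test_ids, 2L)
  expect_identical(splitCohort(ids, seed = 9), splitCohort(ids, seed = 9))
  expect_false(identical(splitCohort(ids, seed = 9)$test_ids,
                         splitCohort(ids, seed = 10)$test_ids))
  expect_error(splitCohort(letters[1:3], seed = 1), "at least 4")
})

test_that("the forest fits separable data and stays at chance on shuffled labels", {
  set.seed(17)
  n <- 200
  x <- data.frame(f1 = c(rnorm(n / 2, -2), rnorm(n / 2, 2)),
                  f2 = rnorm(n))
  y <- rep(c("NON_DEPRESSED", "DEPRESSED"), each = n / 2)
  cfg <- modelConfig(n_trees = 300, seed = 1)
  model <- trainModel(x, y, cfg)
  expect_equal(mean(predict(model, x) == y), 1)  # separable: perfect on train
  expect_length(featureImportance(model), 2L)
  expect_gt(featureImportance(model)["f1"], featureImportance(model)["f2"])
  # labels permuted independently of features: held-out accuracy is binomial
  # noise around 50% (100 test points)
  y_perm <- sample(y)
  model2 <- trainModel(x[1:100, ], y_perm[1:100], cfg)
  acc <- 100 * mean(predict(model2, x[101:200, ]) == y_perm[101:200])
  expect_gte(acc, 35)
  expect_lte(acc, 65)
  expect_error(trainModel(x, rep("DEPRESSED", n), cfg), "single class")
})

test_that("evaluation metrics reproduce the diagnosis-comparison arithmetic", {
  # 16 truly depressed of 27; 15 recovered, 8 false positives
  truth <- rep(c("DEPRESSED", "NON_DEPRESSED"), c(16, 11))
  pred <- c(rep("DEPRESSED", 15), "NON_DEPRESSED",
            rep("DEPRESSED", 8), rep("NON_DEPRESSED", 3))
  rep_ <- evaluatePredictions(pred, truth)
  row <- rep_$per_class[rep_$per_class$class == "DEPRESSED", ]
  expect_equal(row$recall, 93.75)
  expect_equal(row$precision, 100 * 15 / 23, tolerance = 1e-10)
  expect_equal(row$f1, 76.92, tolerance = 1e-4)
  expect_equal(rep_$accuracy, 100 * 18 / 27)
  expect_equal(sum(rep_$confusion), 27L)
  # perfect prediction
  perfect <- evaluatePredictions(truth, truth)
  expect_equal(perfect$accuracy, 100)
  expect_true(all(perfect$per_class$f1 == 100))
  # no predicted positives: precision undefined, not zero
  none <- evaluatePredictions(rep("NON_DEPRESSED", 5),
                              rep(c("DEPRESSED", "NON_DEPRESSED"), c(2, 3)))
  pos_row <- none$per_class[none$per_class$class == "DEPRESSED", ]
  expect_true(is.na(pos_row$precision))
  expect_equal(pos_row$recall, 0)
})

test_that("metrics agree with a count-based oracle and swap symmetrically", {
  set.seed(23)
  for (i in 1:40) {
    n <- sample(5:60, 1)
    truth <- sample(c("DEPRESSED", "NON_DEPRESSED"), n, replace = TRUE)
    truth[1:2] <- c("DEPRESSED", "NON_DEPRESSED")  # both classes present
    pred <- sample(c("DEPRESSED", "NON_DEPRESSED"), n, replace = TRUE)
    r <- evaluatePredictions(pred, truth)
    o <- metricsOracle(pred, truth, "DEPRESSED")
    row <- r$per_class[r$per_class$class == "DEPRESSED", ]
    expect_equal(row$precision, o$precision)
    expect_equal(row$recall, o$recall)
    expect_equal(row$f1, o$f1)
    expect_equal(r$accuracy, o$accuracy)
    # f1 is the harmonic mean of the reported precision/recall rows
    ok <- !is.na(row$precision) && !is.na(row$recall) &&
      row$precision + row$recall > 0
    if (ok) expect_equal(row$f1, f1Score(row$precision, row$recall))
    # swapping the positive class swaps rows, accuracy unchanged
    r2 <- evaluatePredictions(pred, truth, positive = "NON_DEPRESSED")
    expect_equal(r2$accuracy, r$accuracy)
    expect_equal(r2$per_class[r2$per_class$class == "DEPRESSED", -1],
                 row[, -1], ignore_attr = TRUE)
  }
})

test_that("ablation trains one model per group on the common split", {
  sim <- generateCohort(smallSpec(n = 24, days = 5, seed = 6))
  feats <- extractFeatures(sim$bundles)
  labs <- labelCohort(sim$bundles)
  labels <- setNames(labs$phq9_label, labs$participant_id)
  sp <- splitCohort(feats$participant_id, seed = 2)
  cfg <- modelConfig(n_trees = 100, seed = 2)
  acc <- ablationByGroup(feats, labels, sp, cfg)
  expect_named(acc, c("sleep", "activity", "expression", "all"))
  expect_true(all(acc >= 0 & acc <= 100))
  # duplicated identical blocks give identical accuracies under a fixed seed
  g <- featureGroups()
  acc2 <- ablationByGroup(feats, labels, sp, cfg,
                          groups = list(a = g$sleep, b = g$sleep))
  expect_equal(acc2[["a"]], acc2[["b"]])
  expect_error(ablationByGroup(feats, labels, sp, cfg,
                               groups = list(empty = integer(0))),
               "empty feature group")
})

test_that("diagnosis comparison isolates the depressed-class row", {
  preds <- setNames(c(rep("DEPRESSED", 15), "NON_DEPRESSED",
                      rep("DEPRESSED", 8), rep("NON_DEPRESSED", 3)),
                    sprintf("p%02d", 1:27))
  diag <- setNames(rep(c("DEPRESSIVE", "NON_DEPRESSIVE"), c(16, 11)),
                   sprintf("p%02d", 1:27))
  cmp <- compareToDiagnosis(preds, diag)
  expect_equal(cmp$depressed_row$recall, 93.75)
  expect_equal(cmp$n_excluded, 0L)
  # all-negative predictions: zero recall, undefined precision
  cmp2 <- compareToDiagnosis(setNames(rep("NON_DEPRESSED", 27), names(preds)),
                             diag)
  expect_equal(cmp2$depressed_row$recall, 0)
  expect_true(is.na(cmp2$depressed_row$precision))
  # predictions identical to diagnosis: perfect f1
  agree <- setNames(ifelse(diag == "DEPRESSIVE", "DEPRESSED",
                           "NON_DEPRESSED"), names(diag))
  expect_equal(compareToDiagnosis(agree, diag)$depressed_row$f1, 100)
  # missing diagnosis entries are excluded and counted
  diag3 <- diag
  diag3[1:2] <- NA
  expect_equal(compareToDiagnosis(preds, diag3)$n_excluded, 2L)
})

test_that("a fixed seed reproduces the evaluation bit for bit", {
  sim <- generateCohort(smallSpec(n = 16, days = 5, seed = 9))
  feats <- extractFeatures(sim$bundles)
  labs <- labelCohort(sim$bundles)
  labels <- setNames(labs$phq9_label, labs$participant_id)
  run_once <- function() {
    sp <- splitCohort(feats$participant_id, seed = 5)
    fmat <- feats[, featureNames()]
    rownames(fmat) <- feats$participant_id
    m <- trainModel(fmat[sp$train_ids, ], labels[sp$train_ids],
                    modelConfig(n_trees = 150, seed = 5))
    evaluatePredictions(predict(m, fmat[sp$test_ids, ]),
                        labels[sp$test_ids])
  }
  expect_identical(run_once(), run_once())
})
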