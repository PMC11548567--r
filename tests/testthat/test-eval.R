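test_that("stratified folds partition indices with near-equal class counts", {
  labels <- rep(c("normal", "crackle"), each = 5)
  folds <- kfold_split(labels, 5, seed = 1)
  expect_length(folds, 5)
  expect_true(all(lengths(folds) == 2))
  for (f in folds) expect_setequal(labels[f], c("normal", "crackle"))
  expect_setequal(unlist(folds), 1:10)
  expect_equal(sum(lengths(folds)), 10)

  expect_identical(kfold_split(labels, 5, seed = 1), folds)   # determinism
  expect_error(kfold_split(c(rep("normal", 9), "wheeze"), 5), "wheeze")

  # per-class fold counts differ by at most one on ragged sizes
  set.seed(51)
  y <- sample(rep(class_levels(), times = c(17, 11, 8, 7)))
  folds2 <- kfold_split(y, 5, seed = 2)
  expect_setequal(unlist(folds2), seq_along(y))
  expect_true(all(!duplicated(unlist(folds2))))
  for (cl in class_levels()) {
    per_fold <- vapply(folds2, function(f) sum(y[f] == cl), integer(1))
    expect_lte(max(per_fold) - min(per_fold), 1)
  }
})

test_that("reports reproduce exact confusion-matrix arithmetic", {
  conf <- matrix(c(10, 0, 0, 0,
                   0, 9, 1, 0,
                   0, 1, 9, 0,
                   0, 0, 0, 10), 4, 4, byrow = TRUE,
                 dimnames = list(class_levels(), class_levels()))
  rep <- eval_report_from_confusion(conf)
  expect_equal(rep$accuracy, 0.95)
  expect_equal(rep$per_class$recall[3], 0.9)    # wheeze row
  expect_equal(rep$per_class$precision[2], 0.9)
  expect_equal(rep$per_class$support, c(10L, 10L, 10L, 10L))
  expect_equal(sum(rep$confusion), rep$n)
  expect_equal(rep$accuracy, sum(diag(rep$confusion)) / sum(rep$confusion))
})

test_that("degenerate predictors give the forced report values", {
  truth <- rep(class_levels(), each = 5)
  perfect <- eval_report(truth, truth)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$per_class$f1, rep(1, 4))
  expect_true(all(perfect$confusion[row(perfect$confusion) != col(perfect$confusion)] == 0))

  expect_warning(constant <- eval_report(truth, rep("normal", 20)), "undefined")
  expect_equal(constant$accuracy, 0.25)
  expect_equal(constant$per_class$f1[2:4], rep(0, 3))
})

test_that("report metrics agree with a brute-force oracle on random predictions", {
  set.seed(52)
  for (i in 1:25) {
    n <- sample(20:60, 1)
    truth <- sample(class_levels(), n, TRUE)
    pred <- sample(class_levels(), n, TRUE)
    rep <- suppressWarnings(eval_report(truth, pred))
    ora <- oracle_metrics(truth, pred)
    expect_equal(rep$accuracy, ora$accuracy)
    expect_equal(rep$per_class$precision, unname(ora$per_class[, "precision"]))
    expect_equal(rep$per_class$recall, unname(ora$per_class[, "recall"]))
    expect_equal(rep$per_class$f1, unname(ora$per_class[, "f1"]))
  }
})

test_that("micro-averaged recall equals accuracy on single-label data", {
  set.seed(53)
  for (i in 1:100) {
    n <- sample(10:50, 1)
    truth <- sample(class_levels(), n, TRUE)
    pred <- sample(class_levels(), n, TRUE)
    rep <- suppressWarnings(eval_report(truth, pred))
    micro_recall <- sum(diag(rep$confusion)) / sum(rep$confusion)
    expect_equal(micro_recall, rep$accuracy)
  }
})

test_that("cross-validation holds out every sample exactly once and reports five metrics", {
  dm <- random_dm(n_per_class = 10, len = 64, seed = 54, sdev = 0.3)
  cfg <- train_config(epochs = 8, batch_size = 8, learning_rate = 0.005, seed = 1)
  cv <- crossval(dm, tiny_arch(), cfg, k = 5, smote_cfg = NULL, seed = 1)
  expect_length(cv$fold_reports, 5)
  expect_equal(sum(vapply(cv$fold_reports, function(r) r$n, numeric(1))), 40)
  expect_setequal(cv$summary$metric,
                  c("accuracy", "sensitivity", "specificity", "precision", "f1"))
  expect_gte(cv$summary$mean[cv$summary$metric == "accuracy"], 0.9)
  expect_true(all(cv$summary$sd >= 0))
})

test_that("in-fold balancing leaves held-out rows untouched", {
  set.seed(55)
  dm <- dataset_matrix(matrix(rnorm(46 * 64), 46),
                       rep(class_levels(), times = c(20, 12, 8, 6)))
  before <- rlang::hash(dm$X)
  cfg <- train_config(epochs = 2, batch_size = 8, seed = 1)
  cv <- crossval(dm, tiny_arch(), cfg, k = 2, smote_cfg = smote_config(seed = 3),
                 seed = 4)
  expect_identical(rlang::hash(dm$X), before)
  # fold reports cover the original (unbalanced) data only
  expect_equal(sum(vapply(cv$fold_reports, function(r) r$n, numeric(1))), 46)
})
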