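test_that("z-score normalization fits on the training split only", {
  set.seed(1)
  tr <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  z <- zscore_fit_apply(tr)
  expect_equal(unname(colMeans(z$train)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(z$train, 2, sd)), c(1, 1), tolerance = 1e-12)

  # train {0, 10}, apply {5}: centred exactly to zero
  z <- zscore_fit_apply(matrix(c(0, 10), 2, 1), matrix(5, 1, 1))
  expect_equal(as.numeric(z$newdata), 0)
  expect_equal(as.numeric(z$scale), sd(c(0, 10)))  # sample (n-1) convention

  # constant column maps to zero with a warning
  tr2 <- cbind(a = rnorm(5), b = rep(3, 5))
  expect_warning(z <- zscore_fit_apply(tr2, cbind(a = 0, b = 99)), "constant")
  expect_equal(unname(z$train[, "b"]), rep(0, 5))
  expect_equal(unname(z$newdata[, "b"]), 0)
})

test_that("fold assignment balances sizes and respects subject grouping", {
  f <- assign_folds(131, 10, mode = "trial", seed = 4)
  expect_equal(sort(as.integer(table(f))), c(rep(13L, 9), 14L))
  expect_length(f, 131)

  expect_identical(assign_folds(131, 10, seed = 4),
                   assign_folds(131, 10, seed = 4))

  subj <- rep(sprintf("S%02d", 1:45), times = c(rep(3, 41), rep(2, 4)))
  fs <- assign_folds(length(subj), 10, mode = "subject",
                     subject_ids = subj, seed = 4)
  spans <- tapply(fs, subj, function(v) length(unique(v)))
  expect_true(all(spans == 1))

  expect_error(assign_folds(5, 10), class = "canegait_data_error")
})

test_that("confusion-matrix metrics handle perfect and undefined cases", {
  m <- metrics_from_confusion(10, 0, 0, 10)
  expect_equal(unlist(m), c(accuracy = 1, precision = 1, recall = 1, f1 = 1))

  # nothing predicted positive: precision undefined (absent), not zero
  m <- metrics_from_confusion(0, 0, 5, 15)
  expect_true(is.na(m$precision))
  expect_equal(m$recall, 0)
  expect_true(is.na(m$f1))
  expect_equal(m$accuracy, 0.75)

  expect_error(metrics_from_confusion(0, 0, 0, 0),
               class = "canegait_data_error")

  # F1 is symmetric under swapping precision and recall (tp fixed,
  # fp and fn exchanged)
  m1 <- metrics_from_confusion(30, 10, 4, 56)
  m2 <- metrics_from_confusion(30, 4, 10, 56)
  expect_equal(m1$f1, m2$f1)
  expect_equal(m1$precision, m2$recall)
})

test_that("AUC equals the pairwise-comparison probability with ties at one half", {
  lab <- c(rep("frail", 4), rep("robust", 6))
  expect_equal(roc_auc(c(rep(1, 4), rep(0, 6)), lab)$auc, 1)
  expect_equal(roc_auc(rep(0.5, 10), lab)$auc, 0.5)

  # brute-force O(n^2) pair enumeration oracle, including ties
  set.seed(6)
  for (i in 1:20) {
    n <- sample(6:20, 1)
    sc <- sample(seq(0, 1, by = 0.25), n, replace = TRUE)
    la <- sample(c("frail", "robust"), n, replace = TRUE)
    if (length(unique(la)) < 2) next
    pos <- sc[la == "frail"]
    neg <- sc[la == "robust"]
    brute <- mean(outer(pos, neg, function(a, b)
      (a > b) + 0.5 * (a == b)))
    expect_equal(roc_auc(sc, la)$auc, brute)
  }

  # invariance under strictly monotone transforms
  sc <- runif(20)
  la <- rep(c("frail", "robust"), 10)
  expect_equal(roc_auc(exp(3 * sc) + 1, la)$auc, roc_auc(sc, la)$auc)

  expect_error(roc_auc(runif(5), rep("frail", 5)),
               class = "canegait_data_error")
})

test_that("AUC matches an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(14)
  for (i in 1:5) {
    sc <- rnorm(40)
    la <- sample(c("frail", "robust"), 40, replace = TRUE)
    if (length(unique(la)) < 2) next
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = la, predictor = sc, levels = c("robust", "frail"),
      direction = "<", quiet = TRUE)))
    expect_equal(roc_auc(sc, la)$auc, ref, tolerance = 1e-12)
  }
})

test_that("every model family separates a 5-sd two-cluster problem", {
  ft <- make_cluster_table(gap = 5, seed = 2)
  folds <- assign_folds(nrow(ft), 10, seed = 2)
  x <- ft[canegait_features()]
  for (spec in default_model_specs()) {
    cv <- train_eval_cv(x, ft$frail_label, spec, folds, seed = 2)
    expect_gte(cv$avg$accuracy, 0.95)
    # aggregated matrix covers each trial exactly once
    expect_equal(Reduce(`+`, cv$confusion), nrow(ft))
    # fold-level F1 is the harmonic mean of that fold's precision and recall
    fm <- cv$fold_metrics
    ok <- !is.na(fm$f1)
    expect_equal(fm$f1[ok],
                 2 * fm$precision[ok] * fm$recall[ok] /
                   (fm$precision[ok] + fm$recall[ok]))
  }
})

test_that("a training split with one class raises a typed error", {
  ft <- make_cluster_table(n_pos = 5, n_neg = 15, gap = 3, seed = 3)
  # every positive in fold 1: training for fold 1 sees a single class
  folds <- c(rep(1L, 5), rep(1:2, length.out = 15))
  expect_error(
    train_eval_cv(ft[canegait_features()], ft$frail_label,
                  default_model_specs()$lda, folds),
    class = "canegait_single_class_error")
})

test_that("hyperparameter search is seeded and never worse than the default", {
  ft <- make_cluster_table(n_pos = 20, n_neg = 30, gap = 1, seed = 5)
  x <- ft[canegait_features()]
  folds <- assign_folds(nrow(ft), 5, seed = 5)
  spec <- default_model_specs()$knn

  t1 <- hyperparameter_search(spec, x, ft$frail_label, folds, seed = 9,
                              budget = 10)
  t2 <- hyperparameter_search(spec, x, ft$frail_label, folds, seed = 9,
                              budget = 10)
  expect_identical(t1$params, t2$params)

  d <- hyperparameter_search(spec, x, ft$frail_label, folds, seed = 9,
                             budget = 1)
  expect_identical(d$params, spec$params)  # budget 1: default evaluated once
  expect_lte(attr(t1, "cv_loss"), attr(d, "cv_loss"))
})

test_that("the five-model report is deterministic for a fixed seed", {
  ft <- make_cluster_table(n_pos = 15, n_neg = 25, gap = 2, seed = 6)
  r1 <- run_classification(ft, seed = 11, search = FALSE)
  r2 <- run_classification(ft, seed = 11, search = FALSE)
  expect_equal(r1$summary, r2$summary)
  expect_equal(sort(unique(r1$summary$model)),
               c("BOOST", "DT", "KNN", "LDA", "SVM"))
  expect_true(all(r1$summary$auc >= 0 & r1$summary$auc <= 1))
})
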