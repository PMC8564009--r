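study_labels <- factor(rep(c("sirloin", "flank", "shank"),
                           c(200, 160, 195)),
                       levels = c("sirloin", "flank", "shank"))

test_that("stratified split allocates prediction samples proportionally", {
  spec <- split_spec(445, 110, seed = 3)
  idx <- make_split(study_labels, spec)
  expect_length(idx$prediction, 110)
  expect_length(idx$calibration, 445)
  # partition: disjoint and exhaustive
  expect_setequal(c(idx$calibration, idx$prediction), seq_along(study_labels))
  expect_length(intersect(idx$calibration, idx$prediction), 0)
  # per-class counts within 1 of the proportional share (110/555)
  got <- table(study_labels[idx$prediction])
  exact <- table(study_labels) / 555 * 110
  expect_true(all(abs(got - exact) <= 1))
  # determinism
  idx2 <- make_split(study_labels, spec)
  expect_identical(idx, idx2)
  # different seed, different membership
  idx3 <- make_split(study_labels, split_spec(445, 110, seed = 4))
  expect_false(identical(idx$prediction, idx3$prediction))
  expect_error(make_split(study_labels[1:100], spec), "must equal")
})

test_that("stratified folds balance sizes and class proportions", {
  idx <- make_split(study_labels, split_spec(445, 110, seed = 1))
  lab <- study_labels[idx$calibration]
  fold <- msifuse:::stratified_folds(lab, 10, seed = 2)
  sizes <- tabulate(fold, 10)
  expect_true(all(sizes %in% c(44, 45)))          # 445 = 10*44 + 5
  for (cl in levels(lab)) {
    per_fold <- tabulate(fold[lab == cl], 10)
    expect_lte(max(per_fold) - min(per_fold), 1)
  }
  expect_error(msifuse:::stratified_folds(factor(rep("a", 5)), 10),
               "at least k")
})

test_that("perfectly separated blobs cross-validate at 100%", {
  fm <- separable_blobs(n_per_class = 20)
  for (kind in c("lda", "linear_svm", "random_forest")) {
    cv <- cross_validate(fm, classifier_spec(kind), k = 5, seed = 1)
    expect_equal(cv$mean_accuracy, 100)
  }
})

test_that("shuffled labels score near chance for three balanced classes", {
  withr::with_seed(31, {
    x <- matrix(rnorm(150 * 6), 150, 6)
    colnames(x) <- paste0("f", 1:6)
    accs <- vapply(1:5, function(s) {
      lab <- factor(sample(rep(c("a", "b", "c"), each = 50)))
      fm <- feature_matrix(x, rep("MS", 6), lab)
      cross_validate(fm, classifier_spec("lda"), k = 5,
                     seed = s)$mean_accuracy
    }, numeric(1))
    expect_gt(mean(accs), 33.3 - 5)
    expect_lt(mean(accs), 33.3 + 5)
  })
})

test_that("random forest memorizes its calibration set", {
  fm <- separable_blobs(n_per_class = 15, gap = 1.5, seed = 8)
  res <- train_predict(fm, fm, classifier_spec("random_forest"))
  expect_equal(res$accuracy, 100)
})

test_that("confusion rows sum to per-class prediction counts", {
  fm <- separable_blobs(n_per_class = 25, gap = 1, seed = 9)
  idx <- make_split(fm$labels, split_spec(40, 10, seed = 2))
  cal <- msifuse:::subset_fm(fm, idx$calibration)
  pred <- msifuse:::subset_fm(fm, idx$prediction)
  res <- train_predict(cal, pred, classifier_spec("lda"))
  expect_equal(unname(rowSums(res$confusion)),
               unname(as.vector(table(pred$labels))))
  expect_equal(sum(res$confusion), 10)
  # multiclass accuracy equals trace / total
  expect_equal(res$accuracy,
               100 * sum(diag(res$confusion)) / sum(res$confusion))
})

test_that("one-vs-rest metrics match direct substitution", {
  # TP=8, TN=9, FP=1, FN=2 for class 1
  conf <- matrix(c(8, 2, 1, 9), 2, 2, byrow = TRUE,
                 dimnames = list(c("pos", "neg"), c("pos", "neg")))
  m <- confusion_metrics(conf, "pos")
  expect_equal(m[["accuracy"]], 85)
  expect_equal(m[["precision"]], 100 * 8 / 9, tolerance = 1e-9)
  expect_equal(m[["recall"]], 80)
  # perfect diagonal
  perf <- diag(c(5, 7, 9))
  dimnames(perf) <- list(letters[1:3], letters[1:3])
  for (k in 1:3) {
    expect_equal(unname(confusion_metrics(perf, k)), c(100, 100, 100))
  }
  # absent class: flagged undefined, reported as 0
  conf0 <- matrix(c(10, 0, 0, 0), 2, 2,
                  dimnames = list(c("a", "b"), c("a", "b")))
  m0 <- confusion_metrics(conf0, "b")
  expect_equal(m0[["recall"]], 0)
  expect_true("recall" %in% attr(m0, "undefined"))
})

test_that("micro-averaged one-vs-rest accuracy is consistent", {
  conf <- matrix(c(30, 3, 2, 4, 25, 1, 2, 2, 31), 3, 3, byrow = TRUE,
                 dimnames = list(letters[1:3], letters[1:3]))
  total <- sum(conf)
  multiclass <- sum(diag(conf)) / total
  # sum of per-class TP equals trace; micro accuracy over the K binary
  # reductions: each error appears once as FP and once as FN
  per_class <- vapply(1:3, function(k)
    confusion_metrics(conf, k)[["accuracy"]] / 100, numeric(1))
  expect_equal(mean(per_class), 1 - 2 * (1 - multiclass) / 3,
               tolerance = 1e-12)
})

test_that("cross-validation is reproducible from (config, seed)", {
  fm <- separable_blobs(n_per_class = 20, gap = 0.8, seed = 10)
  r1 <- cross_validate(fm, classifier_spec("random_forest", seed = 5),
                       k = 4, seed = 7)
  r2 <- cross_validate(fm, classifier_spec("random_forest", seed = 5),
                       k = 4, seed = 7)
  expect_identical(r1, r2)
})

test_that("classifier spec records the configured hyperparameters", {
  sp <- classifier_spec("linear_svm")
  expect_equal(sp$svm_c, 0.6)
  expect_equal(sp$svm_kernel, "linear")
  expect_equal(sp$svm_multiclass, "one-vs-one")
  rf <- classifier_spec("random_forest")
  expect_equal(rf$rf_n_trees, 160L)
  expect_equal(rf$rf_min_samples_leaf, 1L)
  expect_equal(classifier_spec("lda")$lda_solver, "svd")
})
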