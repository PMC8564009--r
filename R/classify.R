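#' Classifier specification
#'
#' The three classifier configurations used throughout: LDA with the
#' SVD-based solver, a linear-kernel SVM with penalty `C` (default 0.6,
#' the grid-searched value; one-vs-one voting for multiclass, ties going to
#' the lowest class index), and a random forest with 160 trees, `sqrt(p)`
#' candidate features per split and minimum leaf size 1.
#'
#' @param kind `"lda"`, `"linear_svm"` or `"random_forest"`.
#' @param svm_c SVM penalty parameter (default 0.6).
#' @param rf_n_trees number of random-forest trees (default 160).
#' @param seed integer seed recorded in reports and used for any stochastic
#'   fitting (random forest).
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("lda", "linear_svm", "random_forest"),
                            svm_c = 0.6, rf_n_trees = 160L, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(svm_c > 0, rf_n_trees >= 1)
  structure(list(kind = kind, lda_solver = "svd",
                 svm_c = svm_c, svm_kernel = "linear",
                 svm_multiclass = "one-vs-one",
                 rf_n_trees = as.integer(rf_n_trees),
                 rf_max_features = "sqrt", rf_min_samples_leaf = 1L,
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

# fit on (x, y) and return a function(newx) -> factor predictions
fit_classifier <- function(spec, x, y, seed = spec$seed) {
  y <- droplevels(as.factor(y))
  switch(spec$kind,
    lda = {
      # the SVD-based solver is used precisely because fused feature sets
      # are collinear; MASS's advisory warning about that is expected
      m <- withCallingHandlers(
        MASS::lda(x, grouping = y),
        warning = function(w) {
          if (grepl("collinear", conditionMessage(w))) {
            invokeRestart("muffleWarning")
          }
        })
      function(newx) stats::predict(m, newx)$class
    },
    linear_svm = {
      m <- e1071::svm(x, y, kernel = "linear", cost = spec$svm_c,
                      scale = FALSE)
      function(newx) stats::predict(m, newx)
    },
    random_forest = {
      m <- withr::with_seed(seed, randomForest::randomForest(
        x, y, ntree = spec$rf_n_trees,
        mtry = max(1L, floor(sqrt(ncol(x)))),
        nodesize = spec$rf_min_samples_leaf))
      function(newx) stats::predict(m, newx)
    })
}

#' Calibration/prediction split specification
#'
#' The study design: 555 labeled samples split into a calibration set of
#' 445 and a prediction set of 110, drawn stratified so each class
#' contributes proportionally (within one sample, by largest-remainder
#' rounding).
#'
#' @param n_calibration calibration-set size (default 445).
#' @param n_prediction prediction-set size (default 110).
#' @param stratified draw the split stratified by class.
#' @param seed integer seed.
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(n_calibration = 445L, n_prediction = 110L,
                       stratified = TRUE, seed = 1L) {
  stopifnot(n_calibration >= 1, n_prediction >= 1)
  structure(list(n_calibration = as.integer(n_calibration),
                 n_prediction = as.integer(n_prediction),
                 stratified = isTRUE(stratified),
                 seed = as.integer(seed)),
            class = "split_spec")
}

# allocate `total` draws across groups proportional to sizes, exactly,
# by largest remainder; each allocation within +/-1 of the exact share
largest_remainder <- function(sizes, total) {
  exact <- sizes / sum(sizes) * total
  base <- floor(exact)
  left <- total - sum(base)
  if (left > 0) {
    extra <- order(exact - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  base
}

#' Split labeled samples into calibration and prediction sets
#'
#' @param labels factor of class labels (or a `feature_matrix` carrying
#'   labels).
#' @param spec a [split_spec()]; the dataset size must equal
#'   `n_calibration + n_prediction`.
#' @return List with integer index vectors `calibration` and `prediction`
#'   (disjoint, exhaustive).
#' @export
make_split <- function(labels, spec = split_spec()) {
  if (inherits(labels, "feature_matrix")) labels <- labels$labels
  labels <- as.factor(labels)
  n <- length(labels)
  if (n != spec$n_calibration + spec$n_prediction) {
    stop("dataset size (", n, ") must equal n_calibration + n_prediction (",
         spec$n_calibration + spec$n_prediction, ")")
  }
  withr::with_seed(spec$seed, {
    if (spec$stratified) {
      sizes <- table(labels)
      take <- largest_remainder(as.vector(sizes), spec$n_prediction)
      pred <- unlist(lapply(seq_along(sizes), function(i) {
        idx <- which(labels == names(sizes)[i])
        sample(idx, take[i])
      }), use.names = FALSE)
    } else {
      pred <- sample(n, spec$n_prediction)
    }
    list(calibration = sort(setdiff(seq_len(n), pred)),
         prediction = sort(pred))
  })
}

# stratified fold assignment: per class, floor(n_c/k) in every fold and the
# remainder spread over the currently smallest folds, so overall fold sizes
# differ by at most one and per-fold class proportions stay within one
# sample of the global ones
stratified_folds <- function(labels, k, seed) {
  labels <- as.factor(labels)
  counts <- table(labels)
  if (any(counts < k)) {
    stop("every class needs at least k = ", k, " members; smallest has ",
         min(counts))
  }
  withr::with_seed(seed, {
    fold <- integer(length(labels))
    totals <- integer(k)
    for (cl in names(counts)) {
      idx <- sample(which(labels == cl))
      n_c <- length(idx)
      per <- rep(n_c %/% k, k)
      r <- n_c %% k
      if (r > 0) {
        bump <- order(totals, seq_len(k))[seq_len(r)]
        per[bump] <- per[bump] + 1
      }
      fold[idx] <- rep(seq_len(k), per)
      totals <- totals + per
    }
    fold
  })
}

#' Stratified k-fold cross-validation of a classifier
#'
#' Builds stratified folds, and for each fold fits the z-score
#' normalization and the classifier on the other k-1 folds before scoring
#' the held-out fold — normalization is re-fitted inside every fold so no
#' held-out information leaks into the parameters.
#'
#' @param calibration a `feature_matrix` with labels.
#' @param spec a [classifier_spec()].
#' @param k number of folds (default 10).
#' @param seed seed for fold construction (and per-fold stochastic fits).
#' @param sd_type normalization variant, see [zscore_fit()].
#' @return List with `mean_accuracy` (percent), `fold_accuracies` and the
#'   integer `folds` assignment.
#' @export
cross_validate <- function(calibration, spec, k = 10L, seed = 1L,
                           sd_type = "population") {
  stopifnot(inherits(calibration, "feature_matrix"),
            !is.null(calibration$labels))
  fold <- stratified_folds(calibration$labels, k, seed)
  acc <- vapply(seq_len(k), function(f) {
    tr_idx <- which(fold != f)
    te_idx <- which(fold == f)
    tr <- feature_matrix(calibration$x[tr_idx, , drop = FALSE],
                         calibration$modality, calibration$labels[tr_idx])
    te <- feature_matrix(calibration$x[te_idx, , drop = FALSE],
                         calibration$modality, calibration$labels[te_idx])
    z <- zscore_fit_transform(tr, te, sd_type)
    pred <- fit_classifier(spec, z$train$x, tr$labels,
                           seed = (spec$seed * 1009L + f) %% 2147483647L)
    mean(pred(z$apply_to$x) == te$labels)
  }, numeric(1))
  list(mean_accuracy = 100 * mean(acc), fold_accuracies = 100 * acc,
       folds = fold)
}

#' Fit on the calibration set and predict the prediction set
#'
#' Normalization is fitted on the full calibration set and applied to both
#' sets; the classifier is fitted on the normalized calibration set.
#'
#' @param calibration,prediction `feature_matrix` objects with a shared
#'   schema and labels.
#' @param spec a [classifier_spec()].
#' @param sd_type normalization variant, see [zscore_fit()].
#' @return List with `accuracy` (percent), the `confusion` count matrix
#'   (rows = true class, columns = predicted) and the `predicted` factor.
#' @export
train_predict <- function(calibration, prediction, spec,
                          sd_type = "population") {
  stopifnot(inherits(calibration, "feature_matrix"),
            inherits(prediction, "feature_matrix"),
            identical(colnames(calibration$x), colnames(prediction$x)))
  z <- zscore_fit_transform(calibration, prediction, sd_type)
  pred_fn <- fit_classifier(spec, z$train$x, calibration$labels)
  predicted <- factor(pred_fn(z$apply_to$x),
                      levels = levels(calibration$labels))
  truth <- factor(prediction$labels, levels = levels(calibration$labels))
  confusion <- table(truth = truth, predicted = predicted)
  list(accuracy = 100 * mean(predicted == truth),
       confusion = unclass(confusion), predicted = predicted)
}

#' One-vs-rest metrics from a confusion matrix
#'
#' Reduces the K-class confusion matrix to a binary problem for the given
#' class and reports `accuracy = (TP + TN) / (TP + TN + FP + FN)`,
#' `precision = TP / (TP + FP)` and `recall = TP / (TP + FN)`, all in
#' percent. A zero denominator yields 0 and sets the `undefined` attribute.
#'
#' @param confusion K x K count matrix, rows = true class, columns =
#'   predicted class.
#' @param class_index row/column index (or class name) of the positive
#'   class.
#' @return Named numeric vector `(accuracy, precision, recall)` in percent.
#' @export
confusion_metrics <- function(confusion, class_index) {
  confusion <- as.matrix(confusion)
  total <- sum(confusion)
  if (total == 0) stop("empty confusion matrix")
  if (is.character(class_index)) {
    class_index <- match(class_index, rownames(confusion))
  }
  tp <- confusion[class_index, class_index]
  fn <- sum(confusion[class_index, ]) - tp
  fp <- sum(confusion[, class_index]) - tp
  tn <- total - tp - fn - fp
  undefined <- character(0)
  prec <- if (tp + fp == 0) { undefined <- c(undefined, "precision"); 0 }
          else tp / (tp + fp)
  rec <- if (tp + fn == 0) { undefined <- c(undefined, "recall"); 0 }
         else tp / (tp + fn)
  out <- 100 * c(accuracy = (tp + tn) / total, precision = prec,
                 recall = rec)
  if (length(undefined)) attr(out, "undefined") <- undefined
  out
}
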