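#' Feature matrix with modality tags and class labels
#'
#' The tabular container passed between feature extraction, fusion and
#' classification: rows are samples, columns are named features, each
#' feature carries a modality tag (`"MS"`, `"CIELAB"` or `"Texture"`), and
#' rows optionally carry a class label (sirloin / flank / shank).
#'
#' @param x numeric matrix with unique column names.
#' @param modality character vector, one tag per column.
#' @param labels optional factor/character of class labels, one per row.
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(x, modality, labels = NULL) {
  stopifnot(is.matrix(x), is.numeric(x), !is.null(colnames(x)),
            length(modality) == ncol(x))
  if (anyDuplicated(colnames(x))) stop("feature names must be unique")
  if (!is.null(labels)) {
    stopifnot(length(labels) == nrow(x))
    labels <- as.factor(labels)
  }
  structure(list(x = x, modality = as.character(modality), labels = labels),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d samples x %d features [%s]%s\n",
              nrow(x$x), ncol(x$x),
              paste(sprintf("%s:%d", names(table(x$modality)),
                            table(x$modality)), collapse = ", "),
              if (is.null(x$labels)) "" else
                sprintf(", %d classes", nlevels(x$labels))))
  invisible(x)
}

#' Feature-level fusion by column-wise concatenation
#'
#' Concatenates modality blocks that describe the same samples into one
#' high-dimensional feature matrix, preserving block order and modality
#' tags. Blocks must have the same number of rows (and identical row
#' identities/labels where present) and disjoint feature names.
#'
#' @param ... `feature_matrix` objects, or a single list of them.
#' @return A fused `feature_matrix`.
#' @export
fuse <- function(...) {
  blocks <- list(...)
  if (length(blocks) == 1L && !inherits(blocks[[1]], "feature_matrix")) {
    blocks <- blocks[[1]]
  }
  stopifnot(length(blocks) >= 1,
            all(vapply(blocks, inherits, logical(1), "feature_matrix")))
  n <- nrow(blocks[[1]]$x)
  lab <- blocks[[1]]$labels
  for (b in blocks[-1]) {
    if (nrow(b$x) != n) stop("blocks differ in number of rows")
    if (!is.null(lab) && !is.null(b$labels) && !identical(lab, b$labels)) {
      stop("blocks carry different row labels")
    }
    if (is.null(lab)) lab <- b$labels
  }
  x <- do.call(cbind, lapply(blocks, `[[`, "x"))
  if (anyDuplicated(colnames(x))) {
    stop("duplicate feature names across blocks: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  }
  feature_matrix(x, unlist(lapply(blocks, `[[`, "modality")), lab)
}

#' Fit z-score normalization parameters on a training matrix
#'
#' Column means and standard deviations are computed on the training rows
#' only, so that applying them to held-out data leaks no information.
#'
#' @param train a `feature_matrix`.
#' @param sd_type `"population"` (divide by n; default) or `"sample"`
#'   (divide by n - 1).
#' @return List with `mean` and `sd` per column (class `zscore_params`).
#' @export
zscore_fit <- function(train, sd_type = c("population", "sample")) {
  stopifnot(inherits(train, "feature_matrix"))
  sd_type <- match.arg(sd_type)
  if (nrow(train$x) == 0) stop("empty training matrix")
  mu <- colMeans(train$x)
  n <- nrow(train$x)
  ss <- colSums(sweep(train$x, 2, mu)^2)
  sdv <- sqrt(ss / if (sd_type == "population") n else max(n - 1, 1))
  structure(list(mean = mu, sd = sdv, sd_type = sd_type),
            class = "zscore_params")
}

#' Apply fitted z-score parameters to a feature matrix
#'
#' Constant training columns (zero standard deviation) are mapped to 0
#' with a warning rather than dividing by zero.
#'
#' @param fm a `feature_matrix`.
#' @param params a `zscore_params` from [zscore_fit()].
#' @return The transformed `feature_matrix`.
#' @export
zscore_apply <- function(fm, params) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(params, "zscore_params"),
            identical(colnames(fm$x), names(params$mean)))
  const <- params$sd == 0
  sdv <- params$sd
  sdv[const] <- 1
  z <- sweep(sweep(fm$x, 2, params$mean), 2, sdv, `/`)
  if (any(const)) {
    z[, const] <- 0
    warning("constant column(s) mapped to 0: ",
            paste(colnames(fm$x)[const], collapse = ", "))
  }
  feature_matrix(z, fm$modality, fm$labels)
}

#' Fit normalization on a training set and transform both sets
#'
#' @param train training `feature_matrix` (parameters fitted here only).
#' @param apply_to optional second `feature_matrix` transformed with the
#'   training parameters.
#' @inheritParams zscore_fit
#' @return List with `train`, `apply_to` (or `NULL`) and `params`.
#' @export
zscore_fit_transform <- function(train, apply_to = NULL,
                                 sd_type = c("population", "sample")) {
  params <- zscore_fit(train, sd_type)
  list(train = zscore_apply(train, params),
       apply_to = if (is.null(apply_to)) NULL
                  else zscore_apply(apply_to, params),
       params = params)
}
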