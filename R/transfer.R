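#' Fit a radial-kernel cluster-transfer classifier
#'
#' Reproduces the cluster labelling step on new cohorts: the training cohort
#' is split stratified by label (default 75% train / 25% holdout), a
#' radial-basis support vector machine is tuned over a small cost/gamma grid
#' by k-fold cross-validation (default 10-fold) on the training portion, and
#' holdout accuracy is reported. Features are the signature genes, z-scored
#' per gene with the training cohort's parameters.
#'
#' @param train_expr `ExpressionMatrix` (log scale is applied internally:
#'   non-lognorm input is log2(x + 1)-transformed).
#' @param train_labels named vector of cluster labels in \{1, 2\} covering
#'   the samples of `train_expr`.
#' @param features gene ids to use (default: all rows).
#' @param split_fraction fraction of samples in the training portion.
#' @param cv_folds cross-validation folds for the tuning grid.
#' @param seed integer seed; same seed gives the identical split and model.
#' @param cost_grid,gamma_grid hyperparameter grids for the radial kernel.
#' @return A list of class `TransferModel`: `features`, `center`, `scale`
#'   (training standardization), `fit` (the svm object), `cv_accuracy`,
#'   `holdout_accuracy`, `best` (chosen hyperparameters).
#' @export
fit_transfer <- function(train_expr, train_labels, features = NULL,
                         split_fraction = 0.75, cv_folds = 10, seed = 1L,
                         cost_grid = c(0.1, 1, 10), gamma_grid = NULL) {
  v <- expr_values(expr_log2(train_expr))
  labels <- train_labels[colnames(v)]
  if (any(is.na(labels))) stop("train_labels must cover all training samples")
  if (length(unique(labels)) < 2) stop("need at least 2 classes in labels")
  if (is.null(features)) features <- rownames(v)
  features <- intersect(features, rownames(v))
  v <- v[features, , drop = FALSE]
  ctr <- rowMeans(v)
  scl <- apply(v, 1, stats::sd)
  scl[scl == 0] <- 1
  z <- (v - ctr) / scl

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  idx_by_class <- split(seq_along(labels), labels)
  train_idx <- sort(unlist(lapply(idx_by_class, function(ix)
    sample(ix, max(1, round(split_fraction * length(ix)))))))
  test_idx <- setdiff(seq_along(labels), train_idx)
  if (length(unique(labels[train_idx])) < 2)
    stop("a class is absent from the training portion")

  xtr <- t(z[, train_idx, drop = FALSE])
  ytr <- factor(labels[train_idx])
  if (is.null(gamma_grid)) gamma_grid <- (1 / length(features)) * c(0.5, 1, 2)
  grid <- expand.grid(cost = cost_grid, gamma = gamma_grid)
  cv_acc <- vapply(seq_len(nrow(grid)), function(i) {
    set.seed(seed + i)
    m <- e1071::svm(xtr, ytr, kernel = "radial", cost = grid$cost[i],
                    gamma = grid$gamma[i], cross = cv_folds)
    m$tot.accuracy
  }, numeric(1))
  best <- grid[which.max(cv_acc), ]
  fit <- e1071::svm(xtr, ytr, kernel = "radial", cost = best$cost,
                    gamma = best$gamma)
  holdout <- if (length(test_idx)) {
    pred <- stats::predict(fit, t(z[, test_idx, drop = FALSE]))
    mean(pred == factor(labels[test_idx], levels = levels(ytr)))
  } else NA_real_
  structure(list(features = features, center = ctr, scale = scl, fit = fit,
                 cv_accuracy = max(cv_acc) / 100,
                 holdout_accuracy = holdout,
                 best = as.list(best), seed = as.integer(seed)),
            class = "TransferModel")
}

#' @export
print.TransferModel <- function(x, ...) {
  cat(sprintf(
    "TransferModel: %d features, CV accuracy %.3f, holdout accuracy %.3f\n",
    length(x$features), x$cv_accuracy, x$holdout_accuracy))
  invisible(x)
}

#' Predict cluster labels in a validation cohort
#'
#' Features are harmonized to the genes shared between the model and the
#' test cohort (coverage below 50% is an error; missing features enter as 0
#' after standardization, i.e. at the feature mean). By default the test
#' cohort is standardized with its own per-gene parameters, which absorbs
#' global platform shifts between cohorts; set `standardize = "train"` to
#' reuse the training parameters instead.
#'
#' @param model a `TransferModel`.
#' @param test_expr `ExpressionMatrix` of the validation cohort.
#' @param standardize `"cohort"` (default) or `"train"`.
#' @return Named integer vector of labels in \{1, 2\}.
#' @export
predict_labels <- function(model, test_expr, standardize = c("cohort", "train")) {
  standardize <- match.arg(standardize)
  v <- expr_values(expr_log2(test_expr))
  shared <- intersect(model$features, rownames(v))
  coverage <- length(shared) / length(model$features)
  if (coverage < 0.5)
    stop(sprintf("feature coverage %.0f%% below 50%%", 100 * coverage))
  message(sprintf("label transfer feature coverage: %d/%d genes",
                  length(shared), length(model$features)))
  z <- matrix(0, length(model$features), ncol(v),
              dimnames = list(model$features, colnames(v)))
  vs <- v[shared, , drop = FALSE]
  if (standardize == "cohort") {
    ctr <- rowMeans(vs)
    scl <- apply(vs, 1, stats::sd)
    scl[scl == 0] <- 1
  } else {
    ctr <- model$center[shared]
    scl <- model$scale[shared]
  }
  z[shared, ] <- (vs - ctr) / scl
  pred <- stats::predict(model$fit, t(z))
  stats::setNames(as.integer(as.character(pred)), colnames(v))
}
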