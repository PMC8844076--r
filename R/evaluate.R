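#' Stratified cross-validation fold assignment
#'
#' Samples are shuffled within each class and dealt round-robin across folds,
#' so per-class counts differ by at most one between folds and every sample
#' is tested exactly once. Deterministic given the seed.
#'
#' @param y class labels.
#' @param n_folds number of folds (default 5).
#' @param seed RNG seed.
#' @return Integer vector of fold assignments in 1..n_folds.
#' @export
make_folds <- function(y, n_folds = 5, seed = 1) {
  y <- as.factor(y)
  if (n_folds < 2) stop("n_folds must be >= 2")
  counts <- tabulate(y, nlevels(y))
  if (any(counts < n_folds) && n_folds < length(y))
    stop("class '", levels(y)[which(counts < n_folds)[1]], "' has ",
         min(counts), " samples, fewer than ", n_folds,
         " folds; use fewer folds")
  if (n_folds > length(y)) stop("more folds than samples")
  folds <- integer(length(y))
  with_preserved_seed(seed, {
    offset <- 0L
    for (k in seq_len(nlevels(y))) {
      idx <- which(as.integer(y) == k)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- ((offset + seq_along(idx) - 1L) %% n_folds) + 1L
      offset <- offset + length(idx)
    }
  })
  folds
}

#' Confusion-matrix metrics in percent
#'
#' Accuracy = (TP+TN)/total, sensitivity = TP/(TP+FN),
#' specificity = TN/(TN+FP), all x 100, with the stated positive class
#' (conventionally the later disease stage of the pair).
#'
#' @param truth,predicted factors over the same two levels.
#' @param positive the positive-class label.
#' @return Named numeric vector `accuracy`, `sensitivity`, `specificity`
#'   (percent).
#' @export
classification_metrics <- function(truth, predicted, positive) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (!positive %in% truth && !positive %in% predicted)
    stop("positive class '", positive, "' not among labels")
  tp <- sum(truth == positive & predicted == positive)
  tn <- sum(truth != positive & predicted != positive)
  fp <- sum(truth != positive & predicted == positive)
  fn <- sum(truth == positive & predicted != positive)
  c(accuracy = 100 * (tp + tn) / length(truth),
    sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_)
}

#' Train on one fold, evaluate on its test split
#'
#' The whole pipeline — normalization, Fisher filtering, joint selection and
#' the SVM — is fit on the training split only, then frozen and applied to
#' the test split.
#'
#' @param train,test [mm_dataset()] objects with identical features and class
#'   levels.
#' @param positive positive-class label (default: last class level, the later
#'   disease stage).
#' @param ... pipeline arguments forwarded to [mmfs()].
#' @return List with `metrics` (percent), `selected` (feature names per
#'   modality), and `model` (the fitted `mmfs`).
#' @export
train_eval_fold <- function(train, test, positive = NULL, ...) {
  stopifnot(inherits(train, "mm_dataset"), inherits(test, "mm_dataset"))
  missing_cls <- setdiff(unique(as.character(test$y)),
                         unique(as.character(train$y)))
  if (length(missing_cls))
    stop("test class(es) absent from training split: ",
         paste(missing_cls, collapse = ", "))
  if (is.null(positive)) positive <- utils::tail(levels(train$y), 1)
  model <- mmfs(train, ...)
  pred <- predict(model, test)
  list(metrics = classification_metrics(test$y, pred, positive),
       selected = lapply(model$selection$weights, names),
       model = model)
}

#' Cross-validated evaluation of the full pipeline
#'
#' Runs stratified k-fold cross-validation, refitting every stage per fold,
#' and aggregates metrics and per-feature selection frequencies (the count of
#' folds in which each feature was selected — features selected in every fold
#' are the stable biomarker candidates).
#'
#' @param ds an [mm_dataset()].
#' @param n_folds number of folds (default 5).
#' @param seed fold-assignment seed.
#' @param positive positive-class label (default: last class level).
#' @param keep_models keep the per-fold fitted models (default FALSE).
#' @param ... pipeline arguments forwarded to [mmfs()].
#' @return Object of class `mm_cv`: list with `folds` (data.frame of per-fold
#'   metrics), `mean` (named vector), `selected` (per fold, per modality),
#'   `selection_frequency` (named integer vector over all ever-selected
#'   features), `assignment`, `seed`, `n_folds`, `positive`.
#' @export
cross_validate <- function(ds, n_folds = 5, seed = 1, positive = NULL,
                           keep_models = FALSE, ...) {
  stopifnot(inherits(ds, "mm_dataset"))
  assignment <- make_folds(ds$y, n_folds = n_folds, seed = seed)
  if (is.null(positive)) positive <- utils::tail(levels(ds$y), 1)
  fold_rows <- vector("list", n_folds)
  selected <- vector("list", n_folds)
  models <- if (keep_models) vector("list", n_folds) else NULL
  for (f in seq_len(n_folds)) {
    res <- tryCatch(
      train_eval_fold(mm_subset_samples(ds, assignment != f),
                      mm_subset_samples(ds, assignment == f),
                      positive = positive, ...),
      error = function(e)
        stop("fold ", f, ": ", conditionMessage(e), call. = FALSE))
    fold_rows[[f]] <- data.frame(fold = f, t(res$metrics))
    selected[[f]] <- res$selected
    if (keep_models) models[[f]] <- res$model
  }
  folds <- do.call(rbind, fold_rows)
  freq <- table(unlist(lapply(selected, unlist), use.names = FALSE))
  freq <- stats::setNames(as.integer(freq), names(freq))
  freq <- sort(freq, decreasing = TRUE)
  structure(list(folds = folds,
                 mean = colMeans(folds[, c("accuracy", "sensitivity",
                                           "specificity")]),
                 selected = selected, selection_frequency = freq,
                 assignment = assignment, seed = seed, n_folds = n_folds,
                 positive = positive, models = models),
            class = "mm_cv")
}

#' @export
print.mm_cv <- function(x, ...) {
  cat(x$n_folds, "-fold cross-validation (positive class: ", x$positive,
      ")\n", sep = "")
  print(x$folds, row.names = FALSE)
  cat("mean: accuracy ", sprintf("%.1f%%", x$mean["accuracy"]),
      ", sensitivity ", sprintf("%.1f%%", x$mean["sensitivity"]),
      ", specificity ", sprintf("%.1f%%", x$mean["specificity"]), "\n",
      sep = "")
  stable <- names(x$selection_frequency)[x$selection_frequency == x$n_folds]
  if (length(stable))
    cat("selected in every fold: ", paste(stable, collapse = ", "), "\n",
        sep = "")
  invisible(x)
}

#' Flatten a cross-validation report for tabulation
#'
#' @param report an `mm_cv` report.
#' @return data.frame with columns `fold`, `metric`, `value` (percent).
#' @export
cv_long <- function(report) {
  stopifnot(inherits(report, "mm_cv"))
  long <- stats::reshape(report$folds, direction = "long",
                         varying = c("accuracy", "sensitivity",
                                     "specificity"),
                         v.names = "value", timevar = "metric",
                         times = c("accuracy", "sensitivity",
                                   "specificity"), idvar = "fold")
  rownames(long) <- NULL
  long[order(long$fold), c("fold", "metric", "value")]
}
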