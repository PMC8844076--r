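#' Fit the integrated Fisher-score + multi-modal multi-task selection model
#'
#' The full training pipeline on one dataset, in four frozen stages:
#' \enumerate{
#'   \item modality-specific normalization (imaging: min-max; SNP: z-score),
#'   \item Fisher-score prefiltering of the genotype block down to the top-m
#'     features, bringing its width to the level of the imaging block,
#'   \item joint multi-task selection: the weight matrix W of the
#'     G1 + l2,1 regularized objective is fitted over both blocks at once and
#'     the k most important features per modality are kept and reweighted,
#'   \item a linear support vector machine on the reweighted features.
#' }
#' All stages are estimated on the supplied (training) data only; `predict()`
#' applies the frozen parameters to held-out samples, so the model can be
#' refit per cross-validation fold without leakage.
#'
#' @param ds an [mm_dataset()] (training data).
#' @param gamma1 weight of the G1 between-modality penalty (default 0.1 on
#'   normalized data).
#' @param gamma2 weight of the l2,1 row-sparsity penalty (default 0.1).
#' @param k_per_modality selected features per modality (default 5).
#' @param top_m Fisher-filter cutoff for each filtered block; default is the
#'   width of the widest unfiltered block, i.e. the genotype block is reduced
#'   to the size of the imaging block.
#' @param filter_blocks blocks to Fisher-filter (default `"snp"`); blocks not
#'   present in `ds` are ignored.
#' @param schemes per-block normalization schemes, see [normalize_dataset()].
#' @param eps shared denominator/smoothing guard for normalization and Fisher
#'   scoring (default 1e-8).
#' @param eps_smooth solver smoothing constant (default 1e-8).
#' @param max_iter,tol solver budget and relative-objective tolerance.
#' @param cost linear SVM regularization constant (default 1).
#' @param weight_raw multiply the original (pre-normalization) values rather
#'   than the normalized values by the selection weights (default FALSE).
#' @param weight_norm weight normalization scheme, see [select_and_weight()].
#' @param classifier fit the SVM stage (default TRUE; FALSE stops after
#'   selection, e.g. for pure feature-selection studies).
#' @return Object of class `mmfs` with components `norm` (frozen
#'   normalization parameters), `fisher` (per-block reports with retained
#'   sets), `fit` (`W`, objective `trace`, `converged`), `selection`
#'   (an `mm_selection`), `svm`, and bookkeeping (`levels`, `config`,
#'   `feature_names`).
#' @export
#' @examples
#' gen <- generate_cohort(cohort_spec(n_per_class = 20, d_imaging = 10,
#'                                    d_snp = 30, effect_size = 1.5, seed = 1))
#' fit <- mmfs(gen$dataset, k_per_modality = 3)
#' coef(fit)[1:3, ]
#' table(predict(fit, gen$dataset), gen$dataset$y)
mmfs <- function(ds, gamma1 = 0.1, gamma2 = 0.1, k_per_modality = 5,
                 top_m = NULL, filter_blocks = "snp",
                 schemes = c(imaging = "minmax", snp = "zscore"),
                 eps = 1e-8, eps_smooth = 1e-8, max_iter = 200, tol = 1e-6,
                 cost = 1, weight_raw = FALSE,
                 weight_norm = c("sum", "maxabs"), classifier = TRUE) {
  stopifnot(inherits(ds, "mm_dataset"))
  weight_norm <- match.arg(weight_norm)
  cl <- match.call()

  norm <- normalize_dataset(ds, schemes = schemes, eps = eps)
  dsn <- norm$dataset

  filter_blocks <- intersect(filter_blocks, names(ds$blocks))
  if (is.null(top_m)) {
    unfiltered <- setdiff(names(ds$blocks), filter_blocks)
    top_m <- if (length(unfiltered))
      max(vapply(ds$blocks[unfiltered], length, 0L)) else
      min(vapply(ds$blocks, length, 0L))
  }
  fisher <- list()
  keep <- list()
  for (b in filter_blocks) {
    rep_b <- fisher_scores(dsn$X[, dsn$blocks[[b]], drop = FALSE], dsn$y,
                           eps = eps)
    rep_b <- select_top_m(rep_b, min(top_m, length(dsn$blocks[[b]])))
    fisher[[b]] <- rep_b
    keep[[b]] <- rep_b$retained
  }
  ds_red <- if (length(keep)) mm_subset_features(dsn, keep) else dsn

  Y <- label_matrix(ds_red$y)
  fit <- fit_weight_matrix(mm_xt(ds_red), Y, ds_red$blocks,
                           gamma1 = gamma1, gamma2 = gamma2,
                           eps_smooth = eps_smooth, max_iter = max_iter,
                           tol = tol)

  values <- if (weight_raw) {
    raw <- if (length(keep)) mm_subset_features(ds, keep) else ds
    mm_x(raw)
  } else mm_x(ds_red)
  selection <- select_and_weight(fit$W, values, ds_red$blocks,
                                 k_per_modality = k_per_modality,
                                 weight_norm = weight_norm)

  svm_fit <- NULL
  if (classifier)
    svm_fit <- e1071::svm(x = selection$reweighted, y = ds$y,
                          kernel = "linear", cost = cost, scale = FALSE)

  structure(list(call = cl, norm = norm$params, schemes = schemes,
                 fisher = fisher, reduced_blocks = ds_red$blocks,
                 reduced_features = ds_red$feature_names,
                 fit = fit, selection = selection, svm = svm_fit,
                 levels = levels(ds$y),
                 config = list(gamma1 = gamma1, gamma2 = gamma2,
                               k_per_modality = k_per_modality,
                               top_m = top_m, filter_blocks = filter_blocks,
                               eps = eps, eps_smooth = eps_smooth,
                               max_iter = max_iter, tol = tol, cost = cost,
                               weight_raw = weight_raw,
                               weight_norm = weight_norm)),
            class = "mmfs")
}

#' @export
print.mmfs <- function(x, ...) {
  cat("Integrated Fisher-score + multi-modal multi-task selection model\n")
  cat("  classes: ", paste(x$levels, collapse = ", "), "\n", sep = "")
  cat("  gamma1 = ", x$config$gamma1, ", gamma2 = ", x$config$gamma2,
      ", converged: ", x$fit$converged,
      " (", x$fit$iterations, " iterations)\n", sep = "")
  for (b in names(x$selection$selected))
    cat("  selected [", b, "]: ",
        paste(names(x$selection$weights[[b]]), collapse = ", "), "\n",
        sep = "")
  invisible(x)
}

#' @export
summary.mmfs <- function(object, ...) {
  out <- list(config = object$config, converged = object$fit$converged,
              iterations = object$fit$iterations,
              objective = utils::tail(object$fit$trace, 1),
              selection = lapply(object$selection$weights, function(w)
                data.frame(feature = names(w), weight = unname(w))),
              retained = lapply(object$fisher, function(f) f$retained))
  class(out) <- "summary.mmfs"
  out
}

#' @export
print.summary.mmfs <- function(x, ...) {
  cat("Model configuration: gamma1 =", x$config$gamma1,
      ", gamma2 =", x$config$gamma2,
      ", top_m =", x$config$top_m,
      ", k per modality =", x$config$k_per_modality, "\n")
  cat("Solver: converged =", x$converged, "after", x$iterations,
      "iterations; final objective =", format(x$objective), "\n")
  for (b in names(x$selection)) {
    cat("\nSelected features [", b, "] (normalized weights):\n", sep = "")
    print(x$selection[[b]], row.names = FALSE)
  }
  invisible(x)
}

#' Extract the fitted weight matrix
#'
#' @param object an `mmfs` model.
#' @param ... unused.
#' @return The d x c weight matrix over the post-filter feature set, with
#'   feature rownames and class colnames.
#' @export
coef.mmfs <- function(object, ...) object$fit$W

#' Predict class labels for new samples
#'
#' Applies the frozen normalization, Fisher-retained subset, selection and
#' weights to `newdata`, then classifies with the fitted linear SVM.
#'
#' @param object an `mmfs` model fitted with `classifier = TRUE`.
#' @param newdata an [mm_dataset()] with the same feature names and blocks as
#'   the training data.
#' @param ... unused.
#' @return Factor of predicted class labels.
#' @export
predict.mmfs <- function(object, newdata, ...) {
  if (is.null(object$svm))
    stop("model was fitted with classifier = FALSE")
  M <- mmfs_transform(object, newdata)
  stats::predict(object$svm, M)
}

#' Transform new samples into the selected, reweighted feature space
#'
#' @param object an `mmfs` model.
#' @param newdata an [mm_dataset()] compatible with the training data.
#' @return N x k matrix of selected, weighted feature values.
#' @export
mmfs_transform <- function(object, newdata) {
  stopifnot(inherits(object, "mmfs"), inherits(newdata, "mm_dataset"))
  sel_names <- colnames(object$selection$reweighted)
  wvec <- unlist(object$selection$classifier_weights, use.names = FALSE)
  if (object$config$weight_raw) {
    M <- newdata$X[, sel_names, drop = FALSE]
  } else {
    pars <- object$norm[sel_names]
    if (anyNA(names(pars)))
      stop("newdata lacks feature(s): ",
           paste(setdiff(sel_names, newdata$feature_names), collapse = ", "))
    M <- sapply(sel_names, function(f)
      apply_norm(newdata$X[, f], pars[[f]]))
    if (is.null(dim(M))) M <- matrix(M, nrow = 1,
                                     dimnames = list(NULL, sel_names))
  }
  sweep(M, 2, wvec, `*`)
}
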