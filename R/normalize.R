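#' Per-feature normalization parameters
#'
#' Two schemes are supported, both estimated on training samples only and
#' frozen for transform. Min-max rescaling maps a feature to
#' \deqn{\tilde x = (x - x_{\min}) / (x_{\max} - x_{\min} + \epsilon),}
#' so training values fall in \[0, 1) and a constant column maps to 0.
#' Z-scoring maps to
#' \deqn{\tilde x = (x - \bar x) / \sqrt{s^2 + \epsilon},}
#' with \eqn{s^2} the N-1 sample variance; the small \eqn{\epsilon > 0} guards
#' degenerate (zero-spread) columns in both schemes.
#'
#' @param values numeric vector of training values for one feature.
#' @param eps small positive denominator guard (default 1e-8).
#' @return `fit_minmax()` / `fit_zscore()` return a parameter list of class
#'   `norm_params` (scheme, the frozen statistics, and `eps`);
#'   `apply_norm()` returns the transformed values.
#' @export
#' @examples
#' p <- fit_minmax(c(0, 5, 10))
#' apply_norm(c(0, 5, 10), p)   # 0, 0.5, ~1
fit_minmax <- function(values, eps = 1e-8) {
  check_norm_input(values, min_n = 1, eps = eps)
  structure(list(scheme = "minmax", min = min(values), max = max(values),
                 eps = eps), class = "norm_params")
}

#' @rdname fit_minmax
#' @export
fit_zscore <- function(values, eps = 1e-8) {
  check_norm_input(values, min_n = 2, eps = eps)
  structure(list(scheme = "zscore", mean = mean(values),
                 var = stats::var(values), eps = eps),
            class = "norm_params")
}

check_norm_input <- function(values, min_n, eps) {
  if (!is.numeric(values) || length(values) < min_n)
    stop("need at least ", min_n, " training value(s)")
  if (any(!is.finite(values)))
    stop("non-finite value in feature column at position ",
         which(!is.finite(values))[1])
  if (!is.numeric(eps) || eps <= 0) stop("eps must be > 0")
}

#' @rdname fit_minmax
#' @param x values to transform (may be unseen data; no clipping is applied,
#'   so out-of-range values map outside \[0, 1)).
#' @param params frozen `norm_params`.
#' @export
apply_norm <- function(x, params) {
  stopifnot(inherits(params, "norm_params"))
  if (any(!is.finite(x)))
    stop("non-finite value in feature column at position ",
         which(!is.finite(x))[1])
  switch(params$scheme,
         minmax = (x - params$min) / (params$max - params$min + params$eps),
         zscore = (x - params$mean) / sqrt(params$var + params$eps),
         stop("unknown normalization scheme '", params$scheme, "'"))
}

#' Normalize a multi-modal dataset, one scheme per modality
#'
#' Continuous imaging-style blocks default to min-max rescaling; genotype
#' blocks default to z-scoring. Parameters are fit on the supplied dataset
#' (typically a training fold) and returned so the identical transform can be
#' frozen and applied to held-out samples via `params`.
#'
#' @param ds an [mm_dataset()].
#' @param schemes named character vector / list assigning `"minmax"` or
#'   `"zscore"` to every block. Default: `imaging` -> minmax, `snp` -> zscore.
#' @param eps denominator guard passed to the fitters.
#' @param params optional frozen parameters from a previous fit; when given,
#'   no fitting happens and the dataset is transformed with them.
#' @return List with `dataset` (transformed [mm_dataset()], structure and
#'   labels unchanged) and `params` (per-feature list of `norm_params`).
#' @export
normalize_dataset <- function(ds,
                              schemes = c(imaging = "minmax", snp = "zscore"),
                              eps = 1e-8, params = NULL) {
  stopifnot(inherits(ds, "mm_dataset"))
  if (is.null(params)) {
    missing_blocks <- setdiff(names(ds$blocks), names(schemes))
    if (length(missing_blocks))
      stop("no normalization scheme assigned to block(s): ",
           paste(missing_blocks, collapse = ", "))
    bad <- setdiff(unlist(schemes[names(ds$blocks)]), c("minmax", "zscore"))
    if (length(bad))
      stop("unknown normalization scheme(s): ", paste(bad, collapse = ", "))
    params <- vector("list", ncol(ds$X))
    names(params) <- ds$feature_names
    for (b in names(ds$blocks)) {
      fitter <- if (schemes[[b]] == "minmax") fit_minmax else fit_zscore
      for (j in ds$blocks[[b]])
        params[[j]] <- fitter(ds$X[, j], eps = eps)
    }
  } else {
    if (!setequal(names(params), ds$feature_names))
      stop("frozen normalization parameters do not match dataset features")
    params <- params[ds$feature_names]
  }
  Xn <- ds$X
  for (j in seq_len(ncol(Xn))) Xn[, j] <- apply_norm(ds$X[, j], params[[j]])
  list(dataset = mm_replace_x(ds, Xn), params = params)
}

#' Residualize features on nuisance covariates
#'
#' Replaces each feature by its residual from an ordinary least-squares fit on
#' the covariates plus an intercept — the usual pre-adjustment for age, sex,
#' education, intracranial volume and similar nuisance variables in real
#' imaging cohorts. Categorical covariates must already be numerically coded.
#'
#' @param ds an [mm_dataset()].
#' @param covariates data.frame or matrix with one row per sample (matched by
#'   `sample_id` column if present, otherwise by position), numeric columns.
#' @return An [mm_dataset()] with residualized values; structure unchanged.
#' @export
residualize_covariates <- function(ds, covariates) {
  stopifnot(inherits(ds, "mm_dataset"))
  covariates <- as.data.frame(covariates)
  if ("sample_id" %in% names(covariates)) {
    if (!setequal(covariates$sample_id, ds$sample_ids))
      stop("covariate sample IDs do not match dataset")
    covariates <- covariates[match(ds$sample_ids, covariates$sample_id),
                             setdiff(names(covariates), "sample_id"),
                             drop = FALSE]
  }
  if (nrow(covariates) != nrow(ds$X))
    stop("covariate table must have one row per sample")
  C <- if (ncol(covariates) == 0)
    matrix(numeric(0), nrow(covariates), 0) else as.matrix(covariates)
  if (!is.numeric(C)) stop("covariates must be numeric")
  design <- cbind(`(Intercept)` = 1, C)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    dropped <- colnames(design)[qrd$pivot[(qrd$rank + 1):ncol(design)]]
    stop("rank-deficient covariate design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  resid <- ds$X - design %*% qr.coef(qrd, ds$X)
  mm_replace_x(ds, resid)
}
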