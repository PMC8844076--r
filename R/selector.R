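#' Fit the multi-task weight matrix by iteratively reweighted least squares
#'
#' Minimizes the smoothed form of
#' \deqn{\min_{W, b} \frac{1}{2N} \|W^\top X + b \mathbf{1}^\top - Y\|_F^2
#'       + \gamma_1 \|W\|_{G_1} + \gamma_2 \|W\|_{2,1}}
#' by majorize-minimize: each iteration freezes diagonal reweighting terms
#' built from the current row norms (for the l2,1 penalty) and per-class
#' modality-block norms (for the G1 penalty), then solves the resulting
#' regularized linear system for each class column. The per-class intercept
#' `b` is unpenalized and absorbed by centering `X` and `Y`; without it the
#' importance ranking of blocks normalized to a nonzero mean (min-max imaging
#' features) would be driven by feature means rather than class contrast.
#' The squared loss is on the per-sample (1/N) scale so a given
#' \eqn{\gamma} has comparable strength across cohort sizes. Every Euclidean
#' norm is smoothed as \eqn{\sqrt{\| \cdot \|^2 + \epsilon}} so the weights
#' stay defined at zero; the recorded objective trace is this smoothed
#' objective and is monotone non-increasing. Initialization is the
#' deterministic ridge solution with ridge constant
#' \eqn{\gamma_1 + \gamma_2}, so repeated fits are bit-identical.
#'
#' @param X d x N feature matrix (features as rows, samples as columns),
#'   typically normalized.
#' @param Y c x N one-hot label matrix ([label_matrix()]).
#' @param block_map named list of row-index vectors partitioning the d rows
#'   into modality blocks.
#' @param gamma1,gamma2 penalty weights, >= 0 (on the per-sample loss scale).
#' @param eps_smooth smoothing constant inside every square root (default
#'   1e-8).
#' @param max_iter iteration budget (default 200).
#' @param tol relative-objective convergence tolerance (default 1e-6).
#' @param intercept fit an unpenalized per-class intercept (default TRUE).
#' @return List with `W` (d x c), `intercept` (length c), `trace` (smoothed
#'   objective per iteration, first entry at the initializer), `converged`,
#'   `iterations`.
#' @export
fit_weight_matrix <- function(X, Y, block_map, gamma1 = 0.1, gamma2 = 0.1,
                              eps_smooth = 1e-8, max_iter = 200,
                              tol = 1e-6, intercept = TRUE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  d <- nrow(X); n <- ncol(X); cc <- nrow(Y)
  if (ncol(Y) != n)
    stop("dimension mismatch: X has ", n, " samples but Y has ", ncol(Y))
  check_block_map(block_map, d)
  if (gamma1 < 0 || gamma2 < 0) stop("gamma1, gamma2 must be >= 0")
  if (eps_smooth <= 0 || tol <= 0 || max_iter < 1)
    stop("eps_smooth and tol must be > 0, max_iter >= 1")
  if (any(!is.finite(X)) || any(!is.finite(Y)))
    stop("non-finite values entering the solve (iteration 0)")

  xbar <- if (intercept) rowMeans(X) else numeric(d)
  ybar <- if (intercept) rowMeans(Y) else numeric(cc)
  Xc <- X - xbar
  Yc <- Y - ybar

  XXt <- tcrossprod(Xc) / n
  XYt <- tcrossprod(Xc, Yc) / n     # d x c
  block_of <- integer(d)
  for (b in seq_along(block_map)) block_of[block_map[[b]]] <- b

  ridge <- gamma1 + gamma2
  W <- tryCatch(
    solve(XXt + diag(ridge, d), XYt),
    error = function(e)
      stop("initial solve failed (singular system at gamma1 = gamma2 = 0 ",
           "with d > N?): ", conditionMessage(e), call. = FALSE))

  trace <- mm_objective_smooth(W, Xc, Yc, block_map, gamma1, gamma2,
                               eps_smooth, loss_scale = 1 / n)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    row_norms <- sqrt(rowSums(W^2) + eps_smooth)
    for (j in seq_len(cc)) {
      blk_norms <- vapply(block_map,
                          function(b) sqrt(sum(W[b, j]^2) + eps_smooth), 0)
      diag_term <- gamma1 / blk_norms[block_of] + gamma2 / row_norms
      W[, j] <- solve(XXt + diag(diag_term, d), XYt[, j])
    }
    if (any(!is.finite(W)))
      stop("non-finite values entering the solve (iteration ", iter, ")")
    obj <- mm_objective_smooth(W, Xc, Yc, block_map, gamma1, gamma2,
                               eps_smooth, loss_scale = 1 / n)
    trace <- c(trace, obj)
    prev <- trace[length(trace) - 1L]
    if (abs(prev - obj) < tol * max(abs(prev), .Machine$double.eps)) {
      converged <- TRUE
      break
    }
  }
  rownames(W) <- rownames(X)
  colnames(W) <- rownames(Y)
  list(W = W, intercept = as.numeric(ybar - crossprod(W, xbar)),
       trace = trace, converged = converged, iterations = iter)
}

#' Rank, select and reweight features from a fitted weight matrix
#'
#' The relative importance of feature i is \eqn{\sum_j |w_{ij}|}, the sum of
#' absolute weights across class tasks. Within each modality the k most
#' important features are kept (ties broken by ascending original index),
#' their importances are normalized — by default to sum to one within the
#' modality — and each selected feature column is multiplied element-wise by
#' its normalized weight to form the classifier input.
#'
#' @param W fitted d x c weight matrix.
#' @param X_features N x d matrix of feature values (columns aligned with the
#'   rows of `W`) to subset and reweight.
#' @param block_map modality partition of the rows of `W`.
#' @param k_per_modality features to keep per modality (default 5).
#' @param weight_norm `"sum"` (normalize selected importances to sum to 1,
#'   the default) or `"maxabs"` (divide by the largest selected importance).
#' @return Object of class `mm_selection`: list with per-modality `selected`
#'   (row indices into `W`), `selected_within` (indices within the block),
#'   `importance` (full vector), `weights` (normalized, per modality),
#'   `classifier_weights` (the normalized weights rescaled to mean 1 within
#'   each modality — same relative importances, but a feature scale on which
#'   a fixed-cost margin classifier behaves conventionally), and `reweighted`
#'   (N x sum(k) matrix of selected columns, each multiplied element-wise by
#'   its classifier weight).
#' @export
select_and_weight <- function(W, X_features, block_map, k_per_modality = 5,
                              weight_norm = c("sum", "maxabs")) {
  weight_norm <- match.arg(weight_norm)
  W <- as.matrix(W)
  X_features <- as.matrix(X_features)
  check_block_map(block_map, nrow(W))
  if (ncol(X_features) != nrow(W))
    stop("X_features has ", ncol(X_features),
         " columns but W has ", nrow(W), " rows")
  if (k_per_modality < 1) stop("k_per_modality must be >= 1")

  importance <- rowSums(abs(W))
  names(importance) <- rownames(W)
  selected <- list(); weights <- list(); within <- list(); cweights <- list()
  for (b in names(block_map)) {
    ib <- block_map[[b]]
    imp_b <- importance[ib]
    if (max(imp_b) <= 0)
      stop("no informative features in modality '", b,
           "'; increase gamma sensitivity or check normalization")
    k <- min(k_per_modality, length(ib))
    pick <- sort(order(-imp_b, seq_along(imp_b))[seq_len(k)])
    w <- imp_b[pick]
    w <- switch(weight_norm, sum = w / sum(w), maxabs = w / max(w))
    selected[[b]] <- ib[pick]
    within[[b]] <- pick
    weights[[b]] <- stats::setNames(w, rownames(W)[ib[pick]])
    cweights[[b]] <- weights[[b]] / mean(weights[[b]])
  }
  cols <- unlist(selected, use.names = FALSE)
  wvec <- unlist(cweights, use.names = FALSE)
  reweighted <- sweep(X_features[, cols, drop = FALSE], 2, wvec, `*`)
  colnames(reweighted) <- rownames(W)[cols]
  structure(list(selected = selected, selected_within = within,
                 importance = importance, weights = weights,
                 classifier_weights = cweights,
                 weight_norm = weight_norm, reweighted = reweighted),
            class = "mm_selection")
}

#' @export
print.mm_selection <- function(x, ...) {
  cat("Multi-modal feature selection\n")
  for (b in names(x$selected)) {
    nm <- names(x$weights[[b]])
    if (is.null(nm)) nm <- as.character(x$selected[[b]])
    cat("  ", b, ": ",
        paste(sprintf("%s (%.3f)", nm, x$weights[[b]]), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}
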