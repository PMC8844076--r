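#' Structured matrix norms used by the multi-task objective
#'
#' `l21_norm()` is the sum over rows of the row-wise Euclidean norm,
#' \eqn{\|W\|_{2,1} = \sum_i \sqrt{\sum_j w_{ij}^2}}; penalizing it drives
#' whole rows (features) to zero jointly across all class tasks.
#' `g1_norm()` is the group-l1 norm over (class, modality) sub-vectors,
#' \eqn{\|W\|_{G_1} = \sum_{j}^{c} \sum_{m}^{M} \|w_{(m), j}\|_2}: an l2
#' coupling inside each modality with l1 sparsity between modalities, which
#' keeps a weak-but-informative modality from being discarded wholesale.
#'
#' @param W numeric d x c weight matrix (features x classes), finite.
#' @return Non-negative scalar; zero iff `W` is all-zero.
#' @export
#' @examples
#' l21_norm(rbind(c(3, 4), c(0, 0)))          # 5
#' g1_norm(matrix(c(3, 4), 2, 1), list(a = 1:2))  # 5
l21_norm <- function(W) {
  W <- as.matrix(W)
  if (any(!is.finite(W))) stop("W contains non-finite entries")
  sum(sqrt(rowSums(W^2)))
}

#' @rdname l21_norm
#' @param block_map named list of integer vectors partitioning the rows of
#'   `W` into modality blocks.
#' @export
g1_norm <- function(W, block_map) {
  W <- as.matrix(W)
  if (any(!is.finite(W))) stop("W contains non-finite entries")
  check_block_map(block_map, nrow(W))
  total <- 0
  for (j in seq_len(ncol(W)))
    for (b in block_map)
      total <- total + sqrt(sum(W[b, j]^2))
  total
}

check_block_map <- function(block_map, d) {
  idx <- unlist(block_map, use.names = FALSE)
  if (length(idx) != d || anyDuplicated(idx) || !setequal(idx, seq_len(d)))
    stop("block map does not partition the ", d, " rows of W")
  invisible(TRUE)
}

#' Regularized multi-task objective value
#'
#' Evaluates
#' \deqn{\tfrac12 \|W^\top X - Y\|_F^2
#'       + \gamma_1 \|W\|_{G_1} + \gamma_2 \|W\|_{2,1}}
#' for a d x N feature matrix `X` (features as rows), a c x N one-hot label
#' matrix `Y`, and a d x c weight matrix `W`.
#'
#' @param W d x c weight matrix.
#' @param X d x N feature matrix (features as rows, samples as columns).
#' @param Y c x N one-hot label matrix (see [label_matrix()]).
#' @param block_map modality partition of the rows of `W`.
#' @param gamma1 weight of the G1 (between-modality) penalty, >= 0.
#' @param gamma2 weight of the l2,1 (row-sparsity) penalty, >= 0.
#' @return Scalar objective value.
#' @export
mm_objective <- function(W, X, Y, block_map, gamma1, gamma2) {
  W <- as.matrix(W); X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(W) != nrow(X))
    stop("dimension mismatch: W has ", nrow(W), " rows but X has ",
         nrow(X), " features")
  if (ncol(W) != nrow(Y))
    stop("dimension mismatch: W has ", ncol(W), " columns but Y has ",
         nrow(Y), " classes")
  if (ncol(X) != ncol(Y))
    stop("dimension mismatch: X has ", ncol(X), " samples but Y has ",
         ncol(Y))
  if (gamma1 < 0 || gamma2 < 0) stop("gamma1, gamma2 must be >= 0")
  0.5 * sum((crossprod(W, X) - Y)^2) +
    gamma1 * g1_norm(W, block_map) + gamma2 * l21_norm(W)
}

# Smoothed objective used by the IRLS solver: every Euclidean norm ||v|| is
# replaced by sqrt(||v||^2 + eps) so the surrogate stays differentiable at 0.
# loss_scale = 1/N puts the squared loss on the per-sample scale.
mm_objective_smooth <- function(W, X, Y, block_map, gamma1, gamma2, eps,
                                loss_scale = 1) {
  g1 <- 0
  for (j in seq_len(ncol(W)))
    for (b in block_map) g1 <- g1 + sqrt(sum(W[b, j]^2) + eps)
  l21 <- sum(sqrt(rowSums(W^2) + eps))
  loss_scale * 0.5 * sum((crossprod(W, X) - Y)^2) +
    gamma1 * g1 + gamma2 * l21
}
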