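#' Fisher scores for a feature block
#'
#' For feature i with overall mean \eqn{\mu_i}, class means \eqn{\mu_i^k} and
#' class sizes \eqn{n_k}, the score is the ratio of between-class to
#' (class-size-weighted) within-class divergence:
#' \deqn{F(x_i) = \frac{\sum_k n_k (\mu_i^k - \mu_i)^2}
#'                     {\sum_k n_k \sum_j (x_{ij}^k - \mu_i^k)^2 + \epsilon}.}
#' A larger score means the feature separates the classes more strongly; the
#' score is zero iff every class mean equals the overall mean, and the
#' \eqn{\epsilon} guard keeps zero-within-variance features finite (they rank
#' first, as they should).
#'
#' @param X numeric matrix, samples as rows, features as columns.
#' @param y class labels, >= 2 classes, each with >= 1 sample.
#' @param eps small positive guard added to the denominator (default 1e-8).
#' @return Object of class `fisher_report`: list with `scores` (per-feature,
#'   named), `ranking` (feature indices in descending score order, ties by
#'   ascending index), `class_stats` (`n_k`, per-class means, overall means),
#'   and `retained` (NULL until [select_top_m()] is applied).
#' @export
#' @examples
#' X <- cbind(f1 = c(0, 2, 4, 6), f2 = c(1, 1, 1, 1))
#' fisher_scores(X, c("a", "a", "b", "b"))$scores  # 2, 0
fisher_scores <- function(X, y, eps = 1e-8) {
  X <- as.matrix(X)
  y <- as.factor(droplevels(as.factor(y)))
  if (nlevels(y) < 2)
    stop("between-class divergence undefined: need >= 2 classes")
  if (length(y) != nrow(X)) stop("y must have one label per row of X")
  if (any(!is.finite(X))) stop("non-finite values in feature block")
  if (eps <= 0) stop("eps must be > 0")

  n_k <- tabulate(y, nlevels(y))
  mu <- colMeans(X)
  # per-class means: c x d
  G <- rowsum(X, y) / n_k
  s_b <- colSums(n_k * sweep(G, 2, mu)^2)
  # n_k-weighted within-class sum of squares
  centered2 <- (X - G[as.integer(y), , drop = FALSE])^2
  s_w <- colSums(rowsum(centered2, y) * n_k)
  scores <- s_b / (s_w + eps)
  names(scores) <- colnames(X)

  ranking <- order(-scores, seq_along(scores))
  structure(list(scores = scores, ranking = ranking,
                 class_stats = list(n_k = stats::setNames(n_k, levels(y)),
                                    class_means = G, overall_means = mu),
                 retained = NULL, eps = eps),
            class = "fisher_report")
}

#' @export
print.fisher_report <- function(x, ...) {
  cat("Fisher score report: ", length(x$scores), " features\n", sep = "")
  top <- x$ranking[seq_len(min(5, length(x$ranking)))]
  cat("  top scores: ",
      paste(sprintf("%s=%.4g", names(x$scores)[top] %||% top,
                    x$scores[top]), collapse = ", "), "\n", sep = "")
  if (!is.null(x$retained))
    cat("  retained: ", length(x$retained), " features\n", sep = "")
  invisible(x)
}

#' Retain the top-m features by Fisher score
#'
#' Scores are ranked in descending order (ties broken by ascending original
#' index, deterministically); the m best features are retained. The reduced
#' block preserves the original feature order among retained columns. Asking
#' for more features than the block holds warns and retains all.
#'
#' @param report a `fisher_report` from [fisher_scores()].
#' @param m number of features to keep (>= 1).
#' @param X optional feature block to reduce alongside the index set.
#' @return The report with `retained` set to the sorted retained indices,
#'   plus `reduced` (the reduced block) when `X` is supplied.
#' @export
select_top_m <- function(report, m, X = NULL) {
  stopifnot(inherits(report, "fisher_report"))
  if (m < 1) stop("m must be >= 1")
  d <- length(report$scores)
  if (m > d) {
    warning("m = ", m, " exceeds block width ", d, "; retaining all features")
    m <- d
  }
  report$retained <- sort(report$ranking[seq_len(m)])
  if (!is.null(X)) {
    X <- as.matrix(X)
    if (ncol(X) != d) stop("X width does not match the scored block")
    report$reduced <- X[, report$retained, drop = FALSE]
  }
  report
}
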