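#' Multi-modal dataset container
#'
#' Bundles a samples-by-features numeric matrix with a modality partition and
#' per-sample class labels. The in-memory convention is samples-as-rows; the
#' joint selector works on the transposed features-by-samples orientation,
#' which it obtains through [mm_xt()] rather than by reaching into the object.
#'
#' @param X numeric matrix, N samples x d features, no missing values.
#' @param blocks named list of integer vectors giving the feature (column)
#'   indices of each modality. Blocks must be contiguous, non-overlapping and
#'   cover every column.
#' @param y per-sample class labels (coerced to factor, length N). Every
#'   declared class must occur at least once.
#' @param sample_ids character vector of N unique sample identifiers; defaults
#'   to rownames of `X` or `S1..SN`.
#' @param feature_names character vector of d feature names; defaults to
#'   colnames of `X` or per-block generated names.
#'
#' @return An object of class `mm_dataset`: a list with elements `X`, `blocks`,
#'   `y`, `sample_ids`, `feature_names`.
#' @export
#' @examples
#' X <- cbind(matrix(rnorm(20), 10), matrix(rbinom(30, 2, 0.3), 10))
#' ds <- mm_dataset(X, blocks = list(imaging = 1:2, snp = 3:5),
#'                  y = rep(c("A", "B"), each = 5))
#' mm_dim(ds)
mm_dataset <- function(X, blocks, y, sample_ids = NULL, feature_names = NULL) {
  if (!is.matrix(X) || !is.numeric(X))
    stop("X must be a numeric matrix (samples x features)")
  if (anyNA(X) || any(!is.finite(X)))
    stop("X contains missing or non-finite values")
  n <- nrow(X); d <- ncol(X)

  if (is.null(names(blocks)) || any(!nzchar(names(blocks))))
    stop("blocks must be a named list")
  idx <- unlist(blocks, use.names = FALSE)
  if (length(idx) != d || anyDuplicated(idx) || !setequal(idx, seq_len(d)))
    stop("blocks must partition feature columns 1..", d,
         " with no overlap and no gap")
  for (b in names(blocks)) {
    ib <- blocks[[b]]
    if (length(ib) && !identical(as.integer(ib), seq(min(ib), max(ib))))
      stop("block '", b, "' is not a contiguous column range")
    blocks[[b]] <- as.integer(ib)
  }

  y <- as.factor(y)
  if (length(y) != n) stop("y must have one label per sample (", n, ")")
  if (nlevels(y) < 1 || any(tabulate(y, nlevels(y)) == 0))
    stop("every declared class must be present at least once")

  if (is.null(sample_ids)) sample_ids <- rownames(X)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != n) stop("sample_ids must have length ", n)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample IDs: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))

  if (is.null(feature_names)) feature_names <- colnames(X)
  if (is.null(feature_names))
    feature_names <- unlist(lapply(names(blocks), function(b)
      paste0(b, "_", seq_along(blocks[[b]]))), use.names = FALSE)
  feature_names <- as.character(feature_names)
  if (length(feature_names) != d) stop("feature_names must have length ", d)
  if (anyDuplicated(feature_names))
    stop("duplicate feature names: ",
         paste(unique(feature_names[duplicated(feature_names)]), collapse = ", "))

  dimnames(X) <- list(sample_ids, feature_names)
  structure(list(X = X, blocks = blocks, y = y,
                 sample_ids = sample_ids, feature_names = feature_names),
            class = "mm_dataset")
}

#' @export
print.mm_dataset <- function(x, ...) {
  dm <- mm_dim(x)
  cat("Multi-modal dataset: ", dm["N"], " samples x ", dm["d"], " features\n",
      sep = "")
  for (b in names(x$blocks))
    cat("  block '", b, "': ", length(x$blocks[[b]]), " features\n", sep = "")
  cat("  classes: ",
      paste(sprintf("%s (%d)", levels(x$y), tabulate(x$y)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Dataset dimensions
#'
#' @param ds an [mm_dataset()].
#' @return Named integer vector with `N` (samples), `d` (features) and `c`
#'   (classes).
#' @export
mm_dim <- function(ds) {
  stopifnot(inherits(ds, "mm_dataset"))
  c(N = nrow(ds$X), d = ncol(ds$X), c = nlevels(ds$y))
}

#' Feature matrix accessors
#'
#' `mm_x()` returns the samples-by-features matrix; `mm_xt()` the
#' features-by-samples transpose used by the multi-task selector.
#'
#' @param ds an [mm_dataset()].
#' @return A numeric matrix.
#' @export
mm_x <- function(ds) {
  stopifnot(inherits(ds, "mm_dataset"))
  ds$X
}

#' @rdname mm_x
#' @export
mm_xt <- function(ds) t(mm_x(ds))

#' Column indices of one modality block
#'
#' @param ds an [mm_dataset()].
#' @param block block name.
#' @return Integer vector of feature column indices.
#' @export
mm_block_indices <- function(ds, block) {
  stopifnot(inherits(ds, "mm_dataset"))
  if (!block %in% names(ds$blocks))
    stop("unknown modality block '", block, "'; available: ",
         paste(names(ds$blocks), collapse = ", "))
  ds$blocks[[block]]
}

#' Subset a dataset by samples
#'
#' Keeps the block structure intact; validity (every class present) is
#' re-checked on the subset.
#'
#' @param ds an [mm_dataset()].
#' @param i integer or logical sample index.
#' @param drop_levels drop class levels absent from the subset (default FALSE,
#'   so a fold that loses a class fails validation loudly).
#' @return An [mm_dataset()].
#' @export
mm_subset_samples <- function(ds, i, drop_levels = FALSE) {
  stopifnot(inherits(ds, "mm_dataset"))
  y <- ds$y[i]
  if (drop_levels) y <- droplevels(y)
  mm_dataset(ds$X[i, , drop = FALSE], ds$blocks, y,
             sample_ids = ds$sample_ids[i], feature_names = ds$feature_names)
}

#' Subset a dataset by features
#'
#' `keep` is a list mapping block names to indices *within* that block; each
#' retained block keeps its original internal feature order and the blocks are
#' re-packed contiguously in their original block order.
#'
#' @param ds an [mm_dataset()].
#' @param keep named list: per block, integer indices relative to the block
#'   (1-based). Blocks omitted from `keep` are kept whole.
#' @return An [mm_dataset()].
#' @export
mm_subset_features <- function(ds, keep) {
  stopifnot(inherits(ds, "mm_dataset"))
  cols <- integer(0)
  new_blocks <- list()
  at <- 0L
  for (b in names(ds$blocks)) {
    ib <- ds$blocks[[b]]
    within <- if (b %in% names(keep)) sort(as.integer(keep[[b]])) else
      seq_along(ib)
    if (length(within) && (min(within) < 1L || max(within) > length(ib)))
      stop("feature indices for block '", b, "' out of range")
    cols <- c(cols, ib[within])
    new_blocks[[b]] <- at + seq_along(within)
    at <- at + length(within)
  }
  mm_dataset(ds$X[, cols, drop = FALSE], new_blocks, ds$y,
             sample_ids = ds$sample_ids,
             feature_names = ds$feature_names[cols])
}

# internal: replace the value matrix, keeping structure and names
mm_replace_x <- function(ds, X) {
  mm_dataset(X, ds$blocks, ds$y, sample_ids = ds$sample_ids,
             feature_names = ds$feature_names)
}

#' One-hot label matrix
#'
#' Builds the c x N indicator matrix used by the multi-task objective: one
#' column per sample, exactly one 1 per column marking its class.
#'
#' @param y factor of class labels.
#' @return c x N binary matrix with class levels as rownames.
#' @export
label_matrix <- function(y) {
  y <- as.factor(y)
  c <- nlevels(y)
  Y <- matrix(0, c, length(y), dimnames = list(levels(y), NULL))
  Y[cbind(as.integer(y), seq_along(y))] <- 1
  Y
}
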