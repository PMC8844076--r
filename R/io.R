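#' Write a multi-modal dataset to tab-separated files
#'
#' Emits one `<prefix>_<block>.tsv` per modality block (header row of feature
#' names, first column `sample_id`), a `<prefix>_labels.tsv` with columns
#' `sample_id` and `label`, and — when ground truth is supplied — a
#' `<prefix>_truth.json` with the planted informative indices. Files are
#' samples-as-rows regardless of the in-memory orientation.
#'
#' @param ds an [mm_dataset()].
#' @param prefix path prefix for the output files.
#' @param truth optional list of per-block informative indices (as returned by
#'   [generate_cohort()]).
#' @return Invisibly, the character vector of files written.
#' @export
write_dataset <- function(ds, prefix, truth = NULL) {
  stopifnot(inherits(ds, "mm_dataset"))
  written <- character(0)
  for (b in names(ds$blocks)) {
    df <- data.frame(sample_id = ds$sample_ids,
                     ds$X[, ds$blocks[[b]], drop = FALSE],
                     check.names = FALSE)
    f <- paste0(prefix, "_", b, ".tsv")
    utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, f)
  }
  lab <- data.frame(sample_id = ds$sample_ids, label = as.character(ds$y))
  f <- paste0(prefix, "_labels.tsv")
  utils::write.table(lab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  written <- c(written, f)
  if (!is.null(truth)) {
    f <- paste0(prefix, "_truth.json")
    jsonlite::write_json(truth, f, auto_unbox = FALSE, digits = NA)
    written <- c(written, f)
  }
  invisible(written)
}

read_block_tsv <- function(path, integer_coded = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("parse error: empty file ", path)
  df <- tryCatch(
    utils::read.delim(path, check.names = FALSE, fill = FALSE,
                      colClasses = NA, blank.lines.skip = FALSE),
    error = function(e) stop("parse error in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (nrow(df) == 0) stop("parse error: ", path, " has a header but no rows")
  if (names(df)[1] != "sample_id")
    stop("parse error: first column of ", path, " must be 'sample_id'")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("parse error in ", path, ": duplicate sample IDs: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  M <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(M))
    stop("parse error in ", path, ": non-numeric feature values")
  if (anyNA(M)) {
    w <- which(is.na(M), arr.ind = TRUE)[1, ]
    stop("parse error in ", path, ": missing value at row ", w[1],
         ", column '", colnames(M)[w[2]], "'")
  }
  if (integer_coded && !all(M %in% c(0, 1, 2))) {
    w <- which(!(M %in% c(0, 1, 2)), arr.ind = FALSE)[1]
    rc <- arrayInd(w, dim(M))
    stop("parse error in ", path, ": genotype value ", M[w], " at row ",
         rc[1], ", column '", colnames(M)[rc[2]],
         "' (valid values are 0/1/2)")
  }
  rownames(M) <- ids
  M
}

#' Read a multi-modal dataset written by [write_dataset()]
#'
#' The genotype block is validated against the additive 0/1/2 allele-count
#' coding; any other value is a parse error with its row/column location.
#' `read(write(ds))` reproduces `ds` exactly.
#'
#' @param prefix path prefix used when writing.
#' @param blocks block names, in order (default `c("imaging", "snp")`).
#' @param genotype_blocks which blocks must be 0/1/2 coded (default `"snp"`).
#' @return An [mm_dataset()].
#' @export
read_dataset <- function(prefix, blocks = c("imaging", "snp"),
                         genotype_blocks = "snp") {
  mats <- lapply(blocks, function(b)
    read_block_tsv(paste0(prefix, "_", b, ".tsv"),
                   integer_coded = b %in% genotype_blocks))
  names(mats) <- blocks
  ids <- rownames(mats[[1]])
  for (b in blocks[-1])
    if (!identical(rownames(mats[[b]]), ids))
      stop("parse error: sample IDs of block '", b,
           "' do not match block '", blocks[1], "'")

  labf <- paste0(prefix, "_labels.tsv")
  if (!file.exists(labf)) stop("file not found: ", labf)
  if (file.size(labf) == 0) stop("parse error: empty file ", labf)
  lab <- utils::read.delim(labf, check.names = FALSE, fill = FALSE,
                           colClasses = "character")
  if (!all(c("sample_id", "label") %in% names(lab)))
    stop("parse error in ", labf, ": need columns sample_id, label")
  if (!setequal(lab$sample_id, ids))
    stop("parse error: label sample IDs do not match feature files")
  y <- lab$label[match(ids, lab$sample_id)]

  X <- do.call(cbind, mats)
  widths <- vapply(mats, ncol, 0L)
  ends <- cumsum(widths)
  blocks_idx <- Map(function(e, w) seq.int(e - w + 1L, e), ends, widths)
  mm_dataset(X, blocks = blocks_idx, y = y, sample_ids = ids,
             feature_names = unlist(lapply(mats, colnames), use.names = FALSE))
}

#' Read additive-coded genotypes from a PLINK .raw file
#'
#' Consumes the whitespace-delimited dialect produced by
#' `plink --recode A`: six leading columns (FID IID PAT MAT SEX PHENOTYPE)
#' followed by one 0/1/2 allele-count column per variant. Only the IID column
#' and the allele counts are used.
#'
#' @param path path to the `.raw` file.
#' @return Numeric matrix of allele counts, samples as rows (rownames = IID),
#'   variants as columns.
#' @export
read_plink_raw <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("parse error: empty file ", path)
  df <- utils::read.table(path, header = TRUE, check.names = FALSE,
                          fill = FALSE)
  lead <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (!identical(toupper(names(df)[1:6]), lead))
    stop("parse error in ", path, ": expected leading columns ",
         paste(lead, collapse = " "))
  ids <- as.character(df$IID)
  if (anyDuplicated(ids))
    stop("parse error in ", path, ": duplicate sample IDs")
  M <- as.matrix(df[, -(1:6), drop = FALSE])
  storage.mode(M) <- "numeric"
  if (anyNA(M)) {
    w <- which(is.na(M), arr.ind = TRUE)[1, ]
    stop("parse error in ", path, ": missing genotype at row ", w[1],
         ", column '", colnames(M)[w[2]], "'")
  }
  if (!all(M %in% c(0, 1, 2))) {
    w <- which(!(M %in% c(0, 1, 2)))[1]
    rc <- arrayInd(w, dim(M))
    stop("parse error in ", path, ": genotype value ", M[w], " at row ",
         rc[1], ", column '", colnames(M)[rc[2]],
         "' (valid values are 0/1/2)")
  }
  rownames(M) <- ids
  M
}
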