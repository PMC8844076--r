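#' Specification of a synthetic multi-modal cohort
#'
#' Describes a cohort with a continuous "imaging" block and an integer 0/1/2
#' genotype block, each carrying a small planted set of class-informative
#' features. Informative imaging features shift their class-conditional mean
#' by `effect_size` standard deviations; informative SNPs shift their
#' class-conditional minor-allele frequency by `snp_effect`.
#'
#' @param n_per_class subjects per class.
#' @param n_classes number of classes (default 2, class-balanced).
#' @param d_imaging imaging feature count.
#' @param d_snp genotype feature count.
#' @param k_informative_imaging planted informative imaging features
#'   (must be <= `d_imaging`).
#' @param k_informative_snp planted informative SNPs (must be <= `d_snp`).
#' @param effect_size standardized mean shift between consecutive classes on
#'   informative imaging features (unitless; noise sd is 1).
#' @param snp_effect shift in minor-allele frequency between consecutive
#'   classes on informative SNPs (probability units).
#' @param maf base minor-allele frequency of every non-informative SNP and of
#'   the first class on informative SNPs (default 0.3).
#' @param seed RNG seed; same seed gives bit-identical cohorts.
#'
#' @return An object of class `cohort_spec`.
#' @export
#' @examples
#' spec <- cohort_spec(n_per_class = 25, d_imaging = 95, d_snp = 916)
#' gen <- generate_cohort(spec)
#' mm_dim(gen$dataset)
cohort_spec <- function(n_per_class = 25, n_classes = 2,
                        d_imaging = 95, d_snp = 916,
                        k_informative_imaging = min(5, d_imaging),
                        k_informative_snp = min(5, d_snp),
                        effect_size = 1, snp_effect = 0.25,
                        maf = 0.3, seed = 1) {
  spec <- list(n_per_class = as.integer(n_per_class),
               n_classes = as.integer(n_classes),
               d_imaging = as.integer(d_imaging), d_snp = as.integer(d_snp),
               k_informative_imaging = as.integer(k_informative_imaging),
               k_informative_snp = as.integer(k_informative_snp),
               effect_size = as.numeric(effect_size),
               snp_effect = as.numeric(snp_effect),
               maf = as.numeric(maf), seed = as.integer(seed))
  validate_cohort_spec(spec)
  structure(spec, class = "cohort_spec")
}

validate_cohort_spec <- function(spec) {
  with(spec, {
    if (n_per_class < 1) stop("invalid cohort spec: n_per_class must be >= 1")
    if (n_classes < 2) stop("invalid cohort spec: n_classes must be >= 2")
    if (d_imaging < 0 || d_snp < 0)
      stop("invalid cohort spec: block widths must be non-negative")
    if (k_informative_imaging > d_imaging)
      stop("invalid cohort spec: k_informative_imaging (",
           k_informative_imaging, ") exceeds d_imaging (", d_imaging, ")")
    if (k_informative_snp > d_snp)
      stop("invalid cohort spec: k_informative_snp (", k_informative_snp,
           ") exceeds d_snp (", d_snp, ")")
    if (k_informative_imaging < 0 || k_informative_snp < 0)
      stop("invalid cohort spec: informative counts must be non-negative")
    if (maf <= 0 || maf >= 1)
      stop("invalid cohort spec: base minor-allele frequency must be in (0,1)")
    if (snp_effect < 0)
      stop("invalid cohort spec: snp_effect must be non-negative")
    if (maf + (n_classes - 1) * snp_effect > 1)
      stop("invalid cohort spec: maf + (n_classes-1)*snp_effect = ",
           maf + (n_classes - 1) * snp_effect, " exceeds 1")
  })
  invisible(spec)
}

#' Generate a synthetic multi-modal cohort
#'
#' Imaging block: informative features are drawn from class-conditional
#' normals with unit variance whose means step by `effect_size` per class;
#' non-informative features are standard normal in every class. SNP block:
#' each genotype is the sum of two Bernoulli draws (values 0/1/2); informative
#' SNPs use class-specific minor-allele frequencies stepping by `snp_effect`
#' per class, non-informative SNPs share the base frequency. Ground-truth
#' informative indices are returned alongside the dataset, never embedded in
#' it.
#'
#' @param spec a [cohort_spec()].
#' @return List with `dataset` (an [mm_dataset()]) and `truth`, a list of the
#'   planted informative column indices *within each block*
#'   (`truth$imaging`, `truth$snp`).
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) spec <- do.call(cohort_spec, spec)
  validate_cohort_spec(spec)
  N <- spec$n_per_class * spec$n_classes
  cls <- rep(seq_len(spec$n_classes), each = spec$n_per_class)

  with_preserved_seed(spec$seed, {
    info_img <- sort(sample.int(spec$d_imaging, spec$k_informative_imaging))
    info_snp <- sort(sample.int(spec$d_snp, spec$k_informative_snp))

    Ximg <- matrix(stats::rnorm(N * spec$d_imaging), N, spec$d_imaging)
    if (length(info_img))
      Ximg[, info_img] <- Ximg[, info_img] +
        (cls - 1) * spec$effect_size

    maf_mat <- matrix(spec$maf, N, spec$d_snp)
    if (length(info_snp))
      maf_mat[, info_snp] <- spec$maf + (cls - 1) * spec$snp_effect
    Xsnp <- matrix(stats::rbinom(N * spec$d_snp, 2L, maf_mat),
                   N, spec$d_snp)

    X <- cbind(Ximg, Xsnp)
    colnames(X) <- c(sprintf("img_%03d", seq_len(spec$d_imaging)),
                     sprintf("snp_%04d", seq_len(spec$d_snp)))
    ds <- mm_dataset(
      X,
      blocks = list(imaging = seq_len(spec$d_imaging),
                    snp = spec$d_imaging + seq_len(spec$d_snp)),
      y = factor(paste0("C", cls), levels = paste0("C", seq_len(spec$n_classes))),
      sample_ids = sprintf("subj_%04d", seq_len(N)))
    list(dataset = ds, truth = list(imaging = info_img, snp = info_snp))
  })
}
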