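#' Default end-to-end pipeline configuration
#'
#' A single nested list, fully serializable to JSON and back without loss,
#' covering every stage: cohort simulation, normalization, Fisher filtering,
#' joint selection and cross-validated evaluation. Every random behavior in a
#' run traces to the single `seed`.
#'
#' @param seed run seed.
#' @return Nested configuration list of class `mm_config`.
#' @export
default_config <- function(seed = 1) {
  structure(list(
    seed = as.integer(seed),
    cohort = list(n_per_class = 50, n_classes = 2, d_imaging = 95,
                  d_snp = 916, k_informative_imaging = 5,
                  k_informative_snp = 5, effect_size = 1,
                  snp_effect = 0.25, maf = 0.3),
    normalization = list(imaging = "minmax", snp = "zscore",
                         epsilon = 1e-8),
    fisher = list(top_m = NULL, blocks = "snp"),
    selector = list(gamma1 = 0.1, gamma2 = 0.1, eps_smooth = 1e-8,
                    max_iter = 200, tol = 1e-6, k_per_modality = 5,
                    weight_norm = "sum", weight_raw = FALSE),
    evaluation = list(n_folds = 5, cost = 1, positive_class = NULL)
  ), class = "mm_config")
}

config_keys <- function() {
  list(top = c("seed", "cohort", "normalization", "fisher", "selector",
               "evaluation"),
       cohort = c("n_per_class", "n_classes", "d_imaging", "d_snp",
                  "k_informative_imaging", "k_informative_snp",
                  "effect_size", "snp_effect", "maf"),
       normalization = c("imaging", "snp", "epsilon"),
       fisher = c("top_m", "blocks"),
       selector = c("gamma1", "gamma2", "eps_smooth", "max_iter", "tol",
                    "k_per_modality", "weight_norm", "weight_raw"),
       evaluation = c("n_folds", "cost", "positive_class"))
}

#' Validate a pipeline configuration
#'
#' Rejects unknown keys (typo safety) and fills omitted keys with defaults.
#'
#' @param config nested list (e.g. parsed from JSON).
#' @return Validated `mm_config`.
#' @export
validate_config <- function(config) {
  keys <- config_keys()
  unknown <- setdiff(names(config), keys$top)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  base <- default_config(config$seed %||% 1)
  for (section in setdiff(keys$top, "seed")) {
    if (is.null(config[[section]])) next
    bad <- setdiff(names(config[[section]]), keys[[section]])
    if (length(bad))
      stop("unknown key(s) in '", section, "': ",
           paste(bad, collapse = ", "))
    for (k in names(config[[section]]))
      base[[section]][k] <- list(config[[section]][[k]])
  }
  base
}

#' Read / write a pipeline configuration as JSON
#'
#' Round-trips exactly: `read_config(write_config(cfg))` equals `cfg`.
#'
#' @param config an `mm_config`.
#' @param path JSON file path.
#' @return `read_config()` returns a validated `mm_config`;
#'   `write_config()` returns `path` invisibly.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  validate_config(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Run the whole pipeline and write its artifacts
#'
#' Simulates a cohort per the config, writes the dataset, runs a full-data
#' fit (normalization parameters, Fisher report, selection) and the
#' cross-validated evaluation, and records provenance. Re-running with the
#' same config reproduces every numeric output.
#'
#' @param config an `mm_config` (see [default_config()], [read_config()]);
#'   validated before use.
#' @param out_dir output directory (created if needed).
#' @param dataset optionally, an existing [mm_dataset()] to analyse instead
#'   of simulating one (the `cohort` section is then ignored).
#' @return Invisibly, a list with the `dataset`, full-data `model`, `cv`
#'   report and the artifact `files` written.
#' @export
run_pipeline <- function(config = default_config(), out_dir, dataset = NULL) {
  config <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  truth <- NULL

  if (is.null(dataset)) {
    spec <- do.call(cohort_spec, c(config$cohort, list(seed = config$seed)))
    gen <- generate_cohort(spec)
    dataset <- gen$dataset
    truth <- gen$truth
  }
  files <- c(files, write_dataset(dataset, file.path(out_dir, "cohort"),
                                  truth = truth))

  args <- list(gamma1 = config$selector$gamma1,
               gamma2 = config$selector$gamma2,
               k_per_modality = config$selector$k_per_modality,
               top_m = config$fisher$top_m,
               filter_blocks = config$fisher$blocks,
               schemes = c(imaging = config$normalization$imaging,
                           snp = config$normalization$snp),
               eps = config$normalization$epsilon,
               eps_smooth = config$selector$eps_smooth,
               max_iter = config$selector$max_iter,
               tol = config$selector$tol,
               cost = config$evaluation$cost,
               weight_raw = isTRUE(config$selector$weight_raw),
               weight_norm = config$selector$weight_norm)

  model <- do.call(mmfs, c(list(ds = dataset), args))

  norm_file <- file.path(out_dir, "normalization_params.json")
  jsonlite::write_json(lapply(model$norm, unclass), norm_file,
                       auto_unbox = TRUE, digits = NA)
  fisher_file <- file.path(out_dir, "fisher_report.json")
  jsonlite::write_json(lapply(model$fisher, function(f) list(
    feature = names(f$scores), score = unname(f$scores),
    rank = order(f$ranking),
    retained = seq_along(f$scores) %in% f$retained)),
    fisher_file, auto_unbox = FALSE, digits = NA)
  sel_file <- file.path(out_dir, "selection.json")
  jsonlite::write_json(list(
    selected = lapply(model$selection$weights, names),
    importance = lapply(names(model$selection$weights), function(b)
      unname(model$selection$importance[model$selection$selected[[b]]])),
    normalized_weights = lapply(model$selection$weights, unname),
    converged = model$fit$converged,
    objective_trace = model$fit$trace), sel_file,
    auto_unbox = FALSE, digits = NA)

  cv <- do.call(cross_validate,
                c(list(ds = dataset, n_folds = config$evaluation$n_folds,
                       seed = config$seed,
                       positive = config$evaluation$positive_class %||%
                         utils::tail(levels(dataset$y), 1)), args))
  cv_file <- file.path(out_dir, "cv_report.json")
  jsonlite::write_json(list(
    folds = cv$folds, mean = as.list(cv$mean),
    selected = cv$selected,
    selection_frequency = as.list(cv$selection_frequency),
    seed = cv$seed, n_folds = cv$n_folds, positive = cv$positive),
    cv_file, auto_unbox = TRUE, digits = NA)
  cv_tsv <- file.path(out_dir, "cv_report.tsv")
  utils::write.table(cv_long(cv), cv_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  prov_file <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(list(
    config = unclass(config),
    config_hash = config_hash(config),
    seed = config$seed,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("mmselect")),
    timestamp = format(Sys.time(), tz = "UTC")), prov_file,
    auto_unbox = TRUE, digits = NA, null = "null")

  files <- c(files, norm_file, fisher_file, sel_file, cv_file, cv_tsv,
             prov_file)
  invisible(list(dataset = dataset, model = model, cv = cv, files = files))
}

# Order-stable hash of the config via its canonical JSON serialization.
config_hash <- function(config) {
  json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                           null = "null")
  # simple polynomial rolling hash; avoids a digest dependency
  bytes <- as.integer(charToRaw(json))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
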