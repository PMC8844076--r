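Package: mmselect
Title: Multi-Modal Multi-Task Feature Selection with Fisher-Score Prefiltering
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Joint biomarker selection from heterogeneous per-subject feature
    blocks (continuous brain-imaging measures and 0/1/2 SNP allele counts).
    Genotype features are prefiltered by Fisher score, then imaging and
    genetic blocks are jointly reduced by a multi-task objective combining a
    group-l1 (G1) penalty across modalities with an l2,1 row-sparsity penalty,
    solved by iteratively reweighted least squares. Includes modality-specific
    normalization, a synthetic multi-modal cohort generator with planted
    informative features, stratified cross-validated evaluation with a linear
    support vector machine, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
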