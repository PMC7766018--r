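Package: spcca
Title: Sparse PCA and Sparse CCA for Paired Host-Microbiome Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Integrates paired sample-by-feature views -- typically host gene
    expression and microbial functional-category abundances measured on the
    same subjects -- when features vastly outnumber samples. Implements sparse
    principal components analysis and sparse canonical correlation analysis
    via rank-one penalized matrix decomposition with soft-thresholding and
    deflation, classical CCA for low-dimensional problems, the exhaustive
    sub-dimensional CCA subset search, quantile normalization and related
    microarray preprocessing, per-feature Welch differential-expression
    testing with Benjamini-Hochberg correction, a paired-view synthetic data
    generator with planted sparse cross-view factors, and a simulation harness
    scoring support recovery and phenotype separation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    limma,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
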