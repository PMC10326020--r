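Package: ianet
Title: Integrated Association Networks from Ensemble Lasso Multi-Omics Integration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Data-driven integration of paired omics matrices (proteomic,
    transcriptomic, epigenomic) by replicated cross-validated lasso
    regression. Builds ensemble-consensus Robust Lasso Coefficient Matrices
    (RLCMs), extracts condition-specific associations by leave-one-group-out
    (LOGO) differencing, assembles gene-level Integrated Association
    Networks (IANs), ranks genes by summed incident edge weights for
    preranked gene-set enrichment export, and benchmarks inferred
    associations against shuffled-input null models and known-interaction
    lists. Includes a synthetic paired-omics generator with planted sparse
    cross-layer structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
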