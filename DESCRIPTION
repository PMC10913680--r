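Package: omiclink
Title: Sparse Multi-Block Integration of Multi-Omics Data with Automated
    Tuning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Scriptable workflow for integrating two or more omics data
    tables measured on the same samples. Provides upload-time
    pre-filtering (low-count removal, a median-absolute-deviation cap at
    10,000 features, and compositional centered log-ratio preprocessing
    of microbiome count tables), sparse latent-variable models (PCA,
    sparse PCA, PLS, sparse PLS in regression and canonical mode,
    (s)PLS-DA, and multiblock sPLS-DA for supervised multi-omics
    integration), cross-validated tuning of component numbers and
    per-component feature counts with an automated near-zero-variance
    repair loop, data-driven design matrices, and cross-block feature
    association networks exportable as GraphML or JSON. A seeded
    synthetic multi-omics generator with planted latent structure makes
    the whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
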