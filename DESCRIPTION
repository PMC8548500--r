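Package: hetrwr
Title: miRNA-Disease Association Prediction by Random Walk with Restart on
    Degree-Weighted Heterogeneous Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts candidate miRNA-disease associations from a sparse
    binary association matrix. Disease semantic similarity is computed from
    ontology DAGs, miRNA functional similarity from disease-annotation sets,
    and Gaussian interaction profile (GIP) kernels from the association
    matrix itself; the similarities are integrated, the association matrix is
    completed with a weighted K-nearest-known-neighbors (WKNKN) step, and a
    random walk with restart is propagated over two degree-weighted
    heterogeneous networks whose results are fused into a final score for
    every disease-miRNA pair. Includes ROC/PR evaluation with 5-fold and
    leave-one-out cross-validation protocols, a synthetic fixture generator
    with planted block structure, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    optparse,
    readr,
    rlang,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
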