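Package: netrex
Title: Reprogramming Prior Gene Regulatory Networks with Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs context-specific gene regulatory networks (GRNs) by
    reprogramming a prior transcription-factor (TF) to target-gene network
    against context-specific expression data. The core model is network
    component analysis (expression approximated by the product of a sparse
    regulatory-potential matrix and latent TF activities) with an
    l0-regularized objective that penalizes edge additions and removals
    relative to the prior, solved by proximal alternating linearized
    minimization (PALM) with guaranteed descent. Also provides PriorBoost, a
    score that gauges whether a prior network helps relative to an
    expression-only tree-ensemble baseline; expression-independent topology
    quality scores based on protein-protein interactions and Gene Ontology
    annotations of coregulated gene pairs; and a synthetic benchmark
    generator with controlled prior corruption for AUPR/AUROC evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    data.table,
    ranger,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
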