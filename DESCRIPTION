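Package: modact
Title: Gene Co-Expression Modules and Module-Activation Cancer Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A multi-cancer transcriptomic analysis pipeline: filters and
    Z-scales a gene-by-library RNA-seq count matrix, discovers gene
    co-expression modules by size-bounded hierarchical seeding with
    randomized seed expansion and Iterative Signature Algorithm refinement,
    profiles per-cancer module activations with significance testing against
    matched normals, classifies samples by nearest module-activation
    centroid with random-subsample cross-validation ROC metrics, and selects
    and prioritizes biomarker candidates by activation threshold and target
    novelty. Includes a negative-binomial synthetic-data generator with
    planted co-expression blocks so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    limma
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
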