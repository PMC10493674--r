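Package: braincomm
Title: Integrated Ligand-Receptor Communication Scoring and
    Perturbation-Based Subtyping for Brain Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers cell-cell communication between brain cell types from
    single-cell and single-nucleus RNA-seq data by integrating four
    ligand-receptor scoring schemes into a single ISIscore per
    (ligand-receptor pair, sender cell type, receiver cell type), calls
    condition-specific communications (disease, sex, brain region) with a
    Wilcoxon rank-sum test and a log-ratio specificity cutoff, partitions
    disease samples into subtypes from a rank-based ligand-receptor edge
    perturbation matrix via subsampled PAM consensus clustering, and trains
    a gradient-boosted classifier on communication genes. Ships a synthetic
    data generator with planted ground truth so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    cluster,
    igraph,
    jsonlite,
    methods,
    stats,
    utils,
    xgboost,
    yaml
Suggests:
    mclust,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
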