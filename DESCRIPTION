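Package: CTCscope
Title: Single-Cell Transcriptome Classification of Circulating Tumor Cells
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for classifying candidate circulating tumor cells (CTCs)
    from single-cell RNA-seq expression matrices: housekeeping-gene quality
    control, reads-per-million normalization, log transformation and median
    polish, unsupervised hierarchical clustering with intracluster-correlation
    heterogeneity statistics, rank-product differential expression with
    permutation-based false discovery rates, marker-panel class annotation,
    and thresholded signature-selection screens for CTC-enriched and
    extracellular-matrix genes. Includes a seeded synthetic-cohort generator
    that emulates the cell-population structure of a mouse pancreatic cancer
    CTC study (classical, platelet-adhered and proliferative CTC subsets,
    leukocytes, fibroblasts, cell-line cells, diluted bulk-tumor replicates
    and RNA-degraded cells) so the full pipeline can be exercised and
    validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    pracma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    cluster,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
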