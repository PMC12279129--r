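Package: CDHscan
Title: Detection of Maize Chromosomal Drive Haplotypes from
    Genotyping-by-Sequencing Tag Counts
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects large chromosomal drive haplotypes (Ab10, K10L2 and the
    supernumerary B chromosome) in maize from genotyping-by-sequencing (GBS)
    tag-by-taxa count tables. Implements a binned tag-index statistic over
    1 Mb windows, a control-anchored iterative k-means consensus caller with
    stepwise Ab10 -> K10L2 and two-stage B-chromosome pipelines, copy-number
    estimation normalized to single-copy core genes, and a random-forest
    classifier of Ab10 cytological types. Ships a synthetic GBS tag-count
    simulator with known truth so every pipeline stage can be exercised and
    validated without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3),
    SummarizedExperiment
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    randomForest,
    pheatmap,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Sequencing, CopyNumberVariation, StructuralVariation,
    Classification, Clustering, Software
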