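Package: methCompare
Title: Cross-Version Concordance Analysis for Illumina MethylationEPIC Arrays
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for harmonizing and comparing DNA methylation beta-value
    data measured on two versions of the Illumina MethylationEPIC BeadChip
    (EPICv1 and EPICv2) using matched donors. Provides replicate-probe
    collapsing, probe quality flagging, array- and probe-level concordance
    metrics (Spearman correlation, pooled standard deviation, probe
    classification, technical-replicate RMSE and intraclass correlation),
    principal-component variance attribution, reference-based immune
    cell-type deconvolution by constrained projection, linear CpG-coefficient
    scores (epigenetic clocks, inflammation and lifestyle biomarkers) with
    epigenetic age acceleration under version-aware strategies, parametric
    empirical-Bayes batch correction, paired comparison statistics with
    effect sizes, and a fully deterministic synthetic matched-cohort
    generator with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    data.table,
    pracma,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    sva,
    mclust,
    jsonlite,
    withr,
    knitr,
    rmarkdown
biocViews: DNAMethylation, MethylationArray, QualityControl, BatchEffect,
    Epigenetics, Preprocessing
Config/testthat/edition: 3
RoxygenNote: 7.3.3
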