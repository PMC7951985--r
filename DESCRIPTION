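Package: BreakpointHotspots
Title: Genome-Window Modeling of Cancer Structural-Variant Breakpoint Hotspots
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for genome-wide analysis of somatic structural-variant
    breakpoint hotspots. The genome is tiled into non-overlapping 100 kb
    windows, per-window breakpoint densities are computed per cancer type and
    thresholded into hotspot labels at configurable percentile labeling types,
    and interval tracks (non-B DNA structures, transcription factor binding,
    histone modifications, methylation, chromatin accessibility, TADs, genomic
    regions) are engineered into local (100 kb) and distant (1 Mb, "upper_")
    coverage features with binary flags and local-maximum indicators. Random
    Forest classifiers and regressors are evaluated over repeated stratified
    train-test splits with imbalance-aware lift-of-recall and lift-of-precision
    metrics, McFadden pseudo R-squared, Boruta shadow-feature selection, forward
    selection and feature-group ranking. A synthetic-bundle generator with a
    log-linear intensity model and planted ground truth makes every stage of
    the pipeline testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    rtracklayer,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
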