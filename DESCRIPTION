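Package: loopaxis
Title: Genomic Interval Statistics, ChIP Signal Numerics and DSB
    Interference for Meiotic Loop/Axis Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing meiotic double-strand-break (DSB) ChIP
    experiments in budding yeast: interval algebra and consensus calls for
    chromosome-axis definition, a constrained-shuffle permutation test for
    peak-overlap significance, a multi-cutoff peak consolidation cascade
    with hyper-ChIPable blacklisting, binned coverage-track numerics
    (RPKM normalisation, background subtraction, Hann-window smoothing,
    metagene pile-ups, heatmap matrices, percentile partitions, window
    correlations), ChIP-qPCR percent-input quantification, and the DSB
    interference statistic with probe-multiplicity and double-cut-loss
    corrections. A synthetic-data generator emulates hotspot/axis
    landscapes, DSB-dependent bimodal coverage and per-chromatid
    double-cut cohorts so every stage runs against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    BiocGenerics,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
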