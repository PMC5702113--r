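Package: chipTurnover
Title: Sigmoidal Modeling of Time-Course ChIP-Seq Coverage and Locus
    Turnover Kinetics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Models per-locus sequencing coverage across a ChIP-seq (or
    ChEC-seq / XR-seq style) time course with four- or five-parameter
    log-logistic sigmoids, classifies each locus's temporal behavior
    (rise, fall, hill, valley, undefined, eliminated) by an
    extrema-timing prediction algorithm with two-fold fit verification,
    and reports interpretable kinetic parameters: the turnover time
    index (the time at which coverage crosses the midpoint between the
    two plateaus, interpretable as a binding half-life), the
    incorporation rate index (slope at the inflection), and the plateau
    coverages with standard errors. Includes coverage extraction from
    BAM files over BED loci, background- and input-based normalization,
    replicate handling, summary analytics (coverage heatmap matrices,
    category proportions, TTI histograms, genome-feature TTI
    distributions, replicate ratios, genomic TTI cluster bins), and a
    synthetic time-course generator with a truth table for benchmarking
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    Rsamtools,
    GenomicAlignments,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
biocViews: ChIPSeq, Sequencing, TimeCourse, Coverage, Classification
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
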