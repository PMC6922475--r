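Package: SegKinetics
Title: Segmented-Regression Kinetics for Minute-Scale RNA-Seq Time Courses
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Fits continuous piecewise-linear (breakpoint) regression models to
    densely sampled gene-expression time courses, selecting the number of
    breakpoints by BIC under minimum-segment constraints, gating dynamic genes
    by adjusted R-squared (with a permutation-calibrated threshold), and
    classifying fitted trends into an immediate/delayed pattern taxonomy
    (monotonic, peak, dip, cyclic, on/off). Provides cross-species comparison
    statistics: Hodges-Lehmann shifts in breakpoint or peak times with
    Wilcoxon confidence intervals, continuity-corrected two-proportion
    differences, and bootstrap confidence intervals on ratios of median slope
    magnitudes. Includes a negative-binomial synthetic time-course generator
    with known piecewise-linear kinetics for end-to-end validation, plus
    median-ratio normalization, unit-interval scaling, every-k-th-sample
    subsampling, control-overlap and intron/exon change analyses, and a
    config-driven pipeline that writes fit, pattern, census and comparison
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite
Config/testthat/edition: 3
biocViews: TimeCourse, Regression, RNASeq, GeneExpression, Software
RoxygenNote: 7.3.3
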