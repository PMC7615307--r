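Package: sexbiasdev
Title: Consensus Detection of Sex-Biased Gene Expression Across Organ Development
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting, classifying and comparing sex-biased gene
    expression in developmental RNA-seq time series. Implements four
    time-series differential-expression callers (negative-binomial spline and
    factor likelihood-ratio tests, a two-step polynomial regression, and a
    stage-window permutation test), a two-caller consensus rule, stage-wise
    adult/prenatal calls and an extended call set, onset classification of
    male-female difference trajectories by soft clustering, the organ
    specificity index tau with sex-chromosome enrichment tests, cross-species
    conservation of sex-biased gene sets through ortholog maps with
    permutation significance, control-bin module scoring of single-cell
    matrices with per-cell-type Wilcoxon comparisons, and TSS-window
    assignment of regulatory regions to target genes with enrichment tests.
    A companion simulation layer generates every input with known ground
    truth (binomial-thinning signal injection into negative-binomial count
    series, dimorphic-cell-type single-cell matrices, multi-species ortholog
    structure, and regulatory region fixtures) so the whole pipeline can be
    exercised and evaluated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    Matrix,
    e1071,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    methods,
    splines,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
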