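Package: dnburden
Title: De Novo Mutation Burden Analysis for Simplex and Multiplex Trio Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical pipeline for quantifying the contribution of de novo
    mutation to autism in simplex and multiplex family collections from
    whole-genome trio sequencing calls. Implements cell-line genetic drift
    sample QC via a bivariate Gaussian ellipse over power-adjusted de novo
    substitution counts and mean alternative allele ratios; functional
    classification of de novo small variants and CNVs against transcript
    models; normalized ascertainment-differential and percent-contributory
    burden statistics with permutation p-values and bootstrap confidence
    intervals, including mixed-normalization aggregation and direct
    affected-vs-affected comparison; detection-power simulation for de novo
    substitutions (binomial read-count model through a trio genotyper) and for
    de novo deletions (hemizygous-X region-swap through a read-depth caller);
    and a liability contribution model combining per-class burden into
    low-risk, high-risk and overall de novo contribution estimates. A
    synthetic trio-cohort generator with plantable contributory signal and
    cell-line drift contamination makes every stage testable without
    access-controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    Biostrings,
    rtracklayer,
    VariantAnnotation,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    jsonlite
Config/testthat/edition: 3
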