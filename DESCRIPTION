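Package: rilqts
Title: Genome-Wide QTS Mapping of Yield Traits in Recombinant Inbred Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unconditional and conditional genome-wide mapping of quantitative
    trait SNPs (QTS) in biparental recombinant inbred line (RIL) populations
    under a saturated mixed linear model with additive, additive-by-additive
    epistatic, and environment-interaction effects. Provides a single-seed-
    descent RIL genotype simulator (Haldane map function) with effect presets
    calibrated to a published rice yield study, multi-environment trait
    summaries and genotypic correlations, Zhu-style conditional phenotype
    construction, cross-validated single-locus and two-locus candidate
    screening, permutation-calibrated F-tests with experiment-wise error
    control, stepwise model selection, Gibbs-sampler effect estimation, and
    heritability partitioning.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
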