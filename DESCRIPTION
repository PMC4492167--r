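Package: mtmim
Title: Multi-Trait Multiple Interval QTL Mapping for Biparental Inbred-Line Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative trait locus (QTL) analysis in recombinant
    inbred line (RIL) populations: genetic-map handling with Kosambi map-function
    conversions and conditional genotype probabilities for Haley-Knott regression,
    per-trait phenotypic modelling with homoscedastic or per-genotype residual
    variances, broad-sense heritability, trait correlations and path-coefficient
    analysis, and single- and multi-trait multiple interval mapping (MIM and
    MT-MIM) with Cockerham-coded epistasis, forward model search against
    resampled score-statistic genome-wide thresholds, drop-LOD support intervals
    and variance-explained summaries. Includes a synthetic-data generator for
    selfed RIL populations with multi-trait QTL architectures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
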