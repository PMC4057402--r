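Package: mcqtl
Title: Multiple-Line Cross QTL Mapping for Multi-Family Doubled-Haploid Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint QTL linkage mapping across several biparental
    doubled-haploid (DH) families sharing a consensus genetic map.
    Implements the multiple-line cross model with family-specific allele
    substitution effects, forward cofactor selection, likelihood-ratio LOD
    profiles along a cM grid, permutation-based genome-wide significance
    thresholds, LOD fall-off support intervals, estimation of the proportion
    of genotypic variance explained (adjusted R-squared over heritability),
    fivefold cross-validation of that proportion, and a full two-dimensional
    scan for pairwise epistatic interactions with region-based multiple-testing
    correction. A companion simulation module generates multi-family DH
    populations (Haldane meiosis, no interference) and multi-location
    partially replicated field trials with genotype-by-location interaction,
    plus two-stage least-squares adjusted entry means (BLUE-style), ANOVA
    variance components and heritability, so the whole pipeline can be
    exercised and validated without external data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
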