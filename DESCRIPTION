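Package: nciiqtl
Title: Genetic Dissection of Hybrid Performance and Heterosis in NCII Maize Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting hybrid performance and midparent heterosis
    in North Carolina Design II (NCII) maize populations. Provides a synthetic
    NCII data generator (RIL genomes under a Haldane crossover process, two
    near-identical testers, derived hybrid populations and multi-environment
    replicated trials), trial-level phenotype analysis (outlier removal,
    BLUEs, variance components and broad-sense heritability, midparent
    heterosis, GCA/SCA decomposition, correlation and path analysis),
    five-kernel polygenic variance dissection (additive, dominance and three
    epistatic kinships built from closed-form Hadamard identities), whitened
    mixed-model genome scans for main and epistatic QTL with LOD support
    intervals and pleiotropy grouping, and additive-plus-dominance genomic
    prediction under three cross-validation schemes including weighted
    genomic selection with significant markers as fixed effects.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
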