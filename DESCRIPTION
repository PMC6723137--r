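Package: selfdiv
Title: Genetic Diversity and Genetic Load Under Mixed Mating Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Multilocus diversity statistics and neutral expectations for
    populations evolving under selfing, partial selfing, or outcrossing.
    Provides single-locus (He, Ho, Fis) and multilocus (identity
    disequilibrium g2, windowed effective haplotype number) diversity
    statistics on phased SNP genotype matrices, pairwise linkage
    disequilibrium and nonlinear fitting of its decay with genetic
    distance, a neutral forward-in-time simulator of inbred-line
    derivation by selfing (complete crossover interference) that yields
    drift-only credible intervals for post-inbreeding diversity,
    Kaplan-Meier analysis of inbred-line extinction, and a synthetic-data
    generator for populations with known mating-system history and
    optional viability selection.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    survival,
    minpack.lm,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
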