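Package: vhinet
Title: Cross-Infectivity Phenotypes and Virus-Host Infection Network Structure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of full-factorial virus-host cross-infectivity
    experiments in microbial systems, modelled on coccolithophore-virus
    (Emiliania huxleyi / EhV) challenge panels. Computes per-strain
    phenotypes (exponential growth rate, resistance as surviving-cell
    ratio and as progeny-producing virus count, viral production),
    Pearson and one-way ANOVA screens between them, and the structure of
    the binary infection network: NODF nestedness, Barber bipartite
    modularity with a leading-eigenvector detector, and significance
    against an equiprobable null-matrix ensemble. Includes a seeded
    synthetic-data generator that simulates the two-timepoint plate
    experiment from a ground-truth interaction matrix so that every
    stage of the pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
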