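Package: grasspred
Title: Quantitative Genetics of Structured Grass Breeding Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An end-to-end toolkit for reduced-representation SNV data from
    outbred, weakly structured plant populations: quality filtering of
    single-nucleotide variants (depth, missingness, Hardy-Weinberg departure,
    heterozygote read balance), windowed linkage-disequilibrium pruning,
    kinship and genomic-relationship matrices, genotype principal component
    analysis with Tracy-Widom significance tests, trait BLUPs and broad-sense
    heritability from replicated field trials, EMMAX-style mixed-linear-model
    genome-wide association with multi-locus forward-backward selection,
    data-perturbation power simulations, and ridge-regression genome-wide
    prediction under random, training-size, marker-selection and
    cross-subpopulation cross-validation designs. Includes a synthetic-data
    generator emulating the statistical structure of a two-subpopulation
    outbred population so the whole pipeline can be exercised and tested
    without access to real genotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
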