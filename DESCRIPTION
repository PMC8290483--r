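Package: biomepipe
Title: Dual-Domain Amplicon Analysis of Early-Life Gut Microbiota
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for paired bacterial (16S) and fungal (ITS2)
    amplicon surveys of mother-infant cohorts. Implements blank-based reagent
    decontamination with geometric-mean-plus-SD classification and background
    subtraction, low-depth sample filtering, rarefaction-based alpha diversity
    with rank-sum comparison of age bins against an adult reference,
    Bray-Curtis community analysis with a permutation test of a continuous age
    covariate and a distance-to-reference-bin convergence test, mother-infant
    shared-OTU analysis with a resampled unrelated-pair null, genus-level
    differential abundance testing, and a truth-labelled Dirichlet-multinomial
    study generator that emulates age-structured gut community succession for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    vegan
Suggests:
    biomformat,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
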