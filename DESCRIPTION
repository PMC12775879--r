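Package: coalabc
Title: Coalescent Simulation and Approximate Bayesian Computation for
    Uniparental Phylogeography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for reconstructing dispersal histories from uniparentally
    inherited sequences (mitogenomes and male-specific Y-chromosome genes).
    Implements a backward-in-time coalescent simulator for multi-population
    serial-founder scenarios with HKY mutation, the standard sequence summary
    statistics (pairwise differences, segregating sites, rarest-allele moments,
    haplotype and nucleotide diversity, Hudson-style F_ST), Tajima's D and
    Fu's Fs neutrality tests with coalescent-simulation p-values, approximate
    Bayesian computation (ABC) scenario choice by rejection and multinomial
    logistic regression, Beaumont-style local-linear parameter estimation with
    RMAE precision diagnostics, prior-scenario pre-evaluation by PCA and
    posterior-predictive goodness-of-fit, plus a depth-ratio sexing and
    hemizygous variant filtering chain for Y-chromosome data and haplogroup
    frequency summaries.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    nnet,
    yaml,
    ape,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
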