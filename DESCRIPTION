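Package: gcoresib
Title: Odds-Ratio Gene-Gene Interaction Testing in Discordant Sib Pairs
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements the GCORE-sib statistic, a fast odds-ratio-based
    test for SNP-SNP (gene-gene) interaction in discordant sib pairs.
    For each SNP pair the 3x3 two-locus genotype tables of affected and
    unaffected sibs are collapsed to weighted 2x2 allele tables; the test
    contrasts the log odds ratios of the two sib classes, with variance
    derived under the within-family label-exchange (multivariate
    hypergeometric) null. Includes a PLINK text PED/MAP reader, a
    deterministic parallel genome-wide pairwise scan engine, an exhaustive
    within-family permutation oracle, a two-SNP nuclear-family simulator
    with a logistic penetrance model, and scripted type-I-error and power
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    parallel,
    S4Vectors,
    IRanges,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
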