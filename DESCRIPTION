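Package: msymut
Title: Regional Heterogeneity of Mutation Accumulation on the Human Y Chromosome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for regional heterogeneity in the accumulation
    of single-nucleotide mutations along the male-specific portion of the
    human Y chromosome (MSY). From filtered haploid variant calls, a baited-
    fragment manifest and a reference sequence, the package builds a genotype
    matrix, infers a maximum-parsimony phylogeny, assigns every mutation to a
    tree branch by Fitch parsimony, partitions the target region into ~80 kb
    bins of effectively sequenced bases, classifies events by CpG context and
    transition/transversion type, tests per-bin event counts for
    proportionality to sequence amount (chi-square), correlates and regresses
    mutation densities against genomic features, and estimates a
    tip-calibrated strict-clock substitution rate with bootstrap intervals
    and node ages. A coalescent-based synthetic-data generator emulates the
    study design (104 haploid samples, 1.5 Mb in 19 bins, CpG
    hypermutability, two ancient calibration tips) so that every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    phangorn,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
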