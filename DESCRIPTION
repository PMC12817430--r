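Package: seedtrace
Title: Genomic Detection of Direct Seeding and Seed Provenance in
    Structured Plant Populations
Version: 0.1.0
Authors@R:
    person("seedtrace", "developers", email = "seedtrace@example.org",
           role = c("aut", "cre"))
Description: Tools to identify direct-seeded (deliberately sown) plant
    populations and their seed provenance from diploid SNP genotypes.
    Provides a Balding-Nichols simulator of multi-lineage genotype data
    with seed-lot bottlenecks and technical replicates, a VCF quality
    filter cascade with LD thinning and replicate-based genotyping error
    rates, per-individual diversity and inbreeding statistics, pairwise
    F_ST (Weir-Cockerham and Hudson), a maximum-likelihood admixture
    model fitted by EM with cross-validated choice of the number of
    evolutionary significant units, neighbor-joining trees with a
    formalised star-cluster detector for shared homogeneous seed
    sources, and the decision rules (admixture threshold, 100-km
    allochthony rule) that classify populations as natural or seeded.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr
Config/testthat/edition: 3
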