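Package: polySSR
Title: Polyploid SSR and S-Locus Genotype Analysis for Prunus Germplasm
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the genetic characterization of polyploid Prunus
    germplasm from dosage-unaware marker data. Implements presence-based
    per-locus diversity statistics (allele counts, unique alleles,
    polymorphic information content), clone detection and minimal
    discriminating marker-set search; Dice similarity, UPGMA clustering
    with bootstrap supports, cophenetic correlation with permutation
    significance, and principal component analysis of presence/absence
    matrices; S-RNase intron-length-polymorphism allele binning,
    occurrence tables, premature-stop-codon scanning and
    Poisson-corrected peptide divergence; and a polysomic gamete model
    for gametophytic self-incompatibility that predicts
    compatible-pollen fractions for polyploid crosses. A seeded
    simulator generates polyploid SSR and S-locus datasets with known
    clones, hybrids and cluster structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
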