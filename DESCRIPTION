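Package: csdhoney
Title: Honey Bee csd Hypervariable-Region Allele Calling from Honey
    Environmental DNA Amplicons
Version: 1.0.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to identify protein alleles of the Apis mellifera
    complementary sex determiner (csd) hypervariable region (HVR) from
    amplicon sequencing of honey environmental DNA.  Reads are anchored on
    the conserved protein motifs flanking the HVR, trimmed at the DNA
    level, quality- and cluster-filtered, translated and validated into
    protein alleles; downstream analyses cover allele abundance
    thresholds, rarefaction of allele richness, pairwise allele diversity
    (length difference plus amino-acid substitutions), and presence/
    absence sample similarity (Jaccard, hierarchical clustering,
    multidimensional scaling, logistic PCA).  A colony-aware amplicon
    simulator with a semiconductor-style error model (substitutions and
    homopolymer-length indels) provides fully synthetic data with known
    ground truth for testing and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    ape,
    vegan,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
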