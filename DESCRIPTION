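Package: mitorec
Title: Recombination, Diversity and Heteroplasmy Analysis for Fungal
    Mitochondrial Population Genomics
Version: 0.1.0
Authors@R:
    person("Mito", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for population-genomic analysis of circular fungal
    mitochondrial genomes from whole-genome alignments and short reads:
    collapsing assemblies into mitotypes and minimum-spanning haplotype
    networks; nucleotide diversity, Ne*mu under uniparental or biparental
    inheritance, and piN/piS by the modified Nei-Gojobori method with
    bootstrap comparison; a recombination detection battery (four-gamete
    scan and haplotype blocks, linkage-disequilibrium-vs-distance Mantel
    tests, maximum chi-square, pairwise homoplasy index); composite
    likelihood estimation of the population recombination parameter rho
    from a simulated two-locus coalescent lookup table, with a
    reversible-jump MCMC variable-rate map; and a k-mer read classifier
    that estimates heteroplasmy as the proportion of reads matching a
    minor mitotype. A coalescent simulator with recombination and a
    mixed-mitotype read simulator make every stage testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    Biostrings,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    vegan
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
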