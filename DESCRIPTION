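Package: uniparent
Title: Uniparental Marker Analysis for Human Population Genetics
Version: 0.1.0
Authors@R:
    person("J.", "Ostrander", email = "jostrander@example.org",
           role = c("aut", "cre"))
Description: Analysis of uniparental genetic markers (mitochondrial DNA
    HVS-I haplotypes and Y-chromosomal SNP/STR profiles) for human
    population genetics: haplogroup classification against user-supplied
    phylogenies, molecular diversity indices, frequency-spectrum
    neutrality tests (Tajima's D, Fu and Li's D/D*/F/F*, Fu's Fs),
    rho-statistic coalescence dating of mtDNA clades, reduced
    median-joining haplotype networks, haplogroup-frequency PCA and
    Y-STR population distances with neighbour-joining trees, stepwise
    mutation model coalescent simulation of Y-STR haplotypes under
    exponential-growth demography, and Bayesian (BATWING-style) TMRCA
    estimation. Includes a synthetic-data generator emulating a
    four-population study design so that the complete pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    igraph,
    ape,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
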