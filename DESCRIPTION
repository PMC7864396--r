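Package: lentinema
Title: Lentiviral Integration Detection, Secondary siRNA Quantification
    and Comparative-Ct Analysis for Nematode Transduction Experiments
Version: 1.0.0
Authors@R:
    person("Rowan", "Ellis", email = "rowan.ellis@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing lentiviral transduction experiments in
    parasitic nematodes. Implements split-read detection of provirus
    integration junctions in whole-genome sequencing reads with a
    downsampling-based viral-read enrichment test, classification and
    reads-per-million quantification of target-specific secondary siRNAs
    (23-nt, 5'-G reads) from small-RNA sequencing libraries, and
    comparative-Ct (delta-delta-Ct) relative quantification of RT-qPCR
    data with geometric-mean multi-reference normalisation and
    Kruskal-Wallis / Dunn group comparisons. A synthetic-data generator
    produces host genomes with injected provirus, junction-spanning
    reads, small-RNA libraries and Ct tables with machine-readable truth
    sets, so every analysis stage can be validated closed-loop without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
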