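Package: diazoscan
Title: Discovery and Quantification of Heterotrophic Bacterial Diazotrophs in Metagenomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-assembly analysis of ocean metagenomes for heterotrophic
    bacterial diazotrophs (HBDs): competitive read recruitment with
    quartile-trimmed (Q2Q3) coverage and detection statistics, single-copy-gene
    completion/redundancy metrics for metagenome-assembled genomes (MAGs),
    dereplication by average nucleotide identity combined with
    abundance-profile correlation, nifH marker screening with translated
    local alignment, Karlin-Altschul E-values and PROSITE motif validation,
    degenerate-primer compatibility auditing, cells-per-litre abundance
    estimation and regional enrichment testing with Welch's t-test. Includes
    a synthetic-community generator with known truth so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    igraph,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
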