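Package: sparsedbg
Title: Sparse de Bruijn Graphs from HiFi Reads by Minimizer Winnowing
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds bidirected sparse de Bruijn graphs from low-error long
    reads (PacBio HiFi and similar). Reads are homopolymer-compressed, k-mers
    are selected by minimizer winnowing with window size w, selected k-mers
    are named by 128-bit orientation-canonical hashes that form the graph
    nodes, edges join minimizers adjacent in reads, error-induced transitive
    edges are cleaned, non-branching paths are condensed into unitigs, and
    base-space sequence is restored by homopolymer run-length consensus.
    Includes a HiFi-like read simulator with a homopolymer-dominated error
    model and GFA 1.0 output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    Rcpp
LinkingTo: Rcpp
Suggests:
    Biostrings,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
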