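Package: dcbnet
Title: Exhaustive Discovery of Densely Connected Biclusters in Gene Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Exhaustive search for all maximal densely connected biclusters:
    connected, dense subnetworks of a gene interaction network whose member
    genes are co-expressed within a tolerance in sufficiently many conditions
    of an accompanying expression matrix. Includes the breadth-first lattice
    enumeration with co-expression edge pruning, a brute-force verification
    oracle, a core-attachment merging refinement, statistical ranking of
    modules against an empirical co-expression null (truncated normal fit to
    sampled connected subnetworks) and a hypergeometric density null with
    redundancy filtering, Gene Ontology based module-set assessment metrics
    (enrichment ratio, coverage, individual coverage, counts of overlapping
    module pairs supporting different functionalities), and a synthetic
    planted-module generator for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
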