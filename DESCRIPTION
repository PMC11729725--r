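Package: vgstats
Title: Graph-Level and Path-Level Statistics for GFAv1 Variation Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Parses GFAv1 pangenome variation graphs (segments, links, paths
    and walks) into an in-memory bidirected graph model and computes a fixed
    catalog of 108 graph-level metrics, per-path statistics, core/shell/private
    pangenome partitions, exact (hypergeometric) and permutation pangenome
    growth curves, length-weighted sample similarity matrices, and sliding
    window profiles along paths. Includes a seeded synthetic variation-graph
    simulator with per-node ground truth for validation, numeric node-id
    relabeling, and a command-line interface emitting analysis-ready TSV and
    JSON tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
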