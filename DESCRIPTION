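Package: satfam
Title: Satellite Repeat Family Discovery and Chromosomal Distribution Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects tandem repeats in genome assemblies with a wraparound
    dynamic-programming aligner, groups them into satellite families by
    rotation-tolerant similarity clustering under Karlin-Altschul E-value
    statistics, merges and ranks family intervals, infers consensus monomers
    and higher-order repeat periods, and classifies each family's chromosomal
    distribution as dispersed or localized. Includes a deterministic synthetic
    genome simulator that plants satellite arrays with a ground-truth manifest
    so every pipeline stage can be validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    igraph,
    jsonlite,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
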