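Package: genemux
Title: Gene Multi-Network Construction, Backbone Filtering and Consensus
    Community Detection
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds a four-layer gene multi-network (mutual-information
    co-expression, transcription-factor co-targeting, microRNA co-targeting
    and protein-protein interaction) over a shared gene set, sparsifies the
    dense layers with the disparity filter under density, cross-layer balance
    and gold-standard enrichment criteria for the significance level, detects
    gene communities by per-layer and cross-layer consensus clustering, and
    scores the resulting communities by gene-set enrichment, tumor-versus-
    normal differential expression and signature intersection.  A planted
    block-structured generator produces all pipeline inputs for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    limma,
    Matrix,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
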