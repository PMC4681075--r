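Package: tractnet
Title: Structural Connectome Construction and Graph-Theoretical Group Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds binary and density-weighted structural brain networks from
    tractography streamlines and a labelled parcellation, computes node- and
    network-level graph measures (degree, strength, clustering, characteristic
    path length, global and local efficiency, betweenness centrality), derives
    normalized clustering and path length against degree- and strength-
    preserving null models, and performs a two-group statistical comparison
    with Bonferroni correction over nodes, hub identification at mean plus two
    standard deviations, and hemispheric laterality analysis. Includes a
    synthetic-data module that generates parcellations, streamline sets and
    two-group connectome cohorts with planted effects so every pipeline stage
    is testable without subject data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
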