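Package: votenet
Title: Vote-Count Meta-Analysis of Differential Expression Lists with a
    Connectivity-Weighted Overlap Null
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrative prioritization of genes reported across independent
    transcriptomic case-control studies. Per-study differentially expressed
    gene (DEG) lists are filtered, mapped to a common identifier and merged;
    genes are ranked by vote counting (number of agreeing study lists, samples
    in agreement, mean fold change); the significance of the cross-study
    overlap is assessed against an empirical Monte Carlo null in which gene
    lists are resampled from the expression universe either uniformly or
    weighted by topological-overlap-based co-expression connectivity; dense
    protein-protein interaction subnetworks are detected with an MCODE-style
    algorithm and hub genes called by normalized betweenness centrality; and
    published in-vivo perturbation evidence is classified into detrimental,
    beneficial or no-effect support per gene. A seed-deterministic synthetic
    data generator produces DEG lists with planted consistent genes, a
    block-correlated expression matrix, an interaction graph with planted
    complexes and a perturbation table, so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
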