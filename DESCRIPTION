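Package: lwcent
Title: Influential-Node Ranking with Entropy-Weighted Local Attributes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies influential (super-spreader) nodes in undirected
    networks with a multiple-local-attributes weighted centrality (LWC):
    degree, clustering coefficient, two-hop degree and two-hop clustering
    coefficient are combined into a single score with weights derived from
    the Shannon entropy of each attribute's distribution across nodes.
    Includes the classical comparison centralities (degree, betweenness,
    closeness, local centrality, clustered local degree), a discrete-time
    SIR (susceptible-infected-recovered) Monte-Carlo spreading oracle that
    defines ground-truth node influence, and ranking-evaluation metrics
    (monotonicity, CCDF, Kendall tau-a, imprecision function, top-k Jaccard
    similarity), plus Erdos-Renyi and Barabasi-Albert generators and named
    toy fixtures for fully reproducible experiments. All per-node results
    are returned as tibbles keyed by node label.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
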