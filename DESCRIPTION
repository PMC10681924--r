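Package: netpharm
Title: Network Pharmacology Screening for Multi-Component Agents
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable, fully offline network-pharmacology screening
    pipeline for multi-component agents such as essential oils: rule-based
    ADMET filtering of GC-MS-identified compounds, molecular weight from
    elemental formulas, disease/drug target-set union and intersection,
    compound-target bipartite networks, score-thresholded protein-protein
    interaction graphs with from-scratch degree, betweenness, closeness and
    eigenvector centralities, iterative above-median core-subnetwork
    extraction, hypergeometric over-representation analysis with
    Benjamini-Hochberg correction, four-parameter logistic IC50 estimation
    from viability plates, and seeded synthetic-data generators that plant
    recoverable ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
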