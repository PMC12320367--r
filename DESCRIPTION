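Package: tamnet
Title: Network-Motif Target Prioritization for Macrophage Drug Repurposing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Prioritizes drug-repurposing targets in tumor-associated
    macrophages (TAMs) from a directed regulatory network and expression
    data. Prunes the network by average TPM, gates TAM cells and runs a
    Wilcoxon rank-sum differential expression test with Bonferroni
    correction, enumerates feedback and feed-forward loop motifs with at
    most four nodes, scores each motif by a weighted combination of mean
    log2 fold change, betweenness centrality and node degree over a weight
    sweep, extracts the Pareto-optimal top-ranked motifs into a core
    network, filters candidate targets by expression and annotation rules,
    and ranks externally produced pharmacophore FIT and docking-energy
    tables into a drug-target shortlist. Ships a seeded synthetic-data
    generator with planted motifs, fold changes and screening hits so the
    whole pipeline is testable without downloads.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
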