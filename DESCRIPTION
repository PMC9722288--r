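Package: netpharm
Title: Network Pharmacology Screening of Herbal Compound-Target-Pathway Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A local, fully testable network-pharmacology screening chain for
    multi-compound herbal medicines: compound library ingestion and
    PubChem-CID deduplication, rule-based drug-likeness screening (Lipinski,
    Ghose, Veber, Egan, Muegge) with an ellipse-based gastrointestinal
    absorption classifier, compound-target and disease-target set algebra with
    Venn partitions, protein-protein interaction centrality analysis with a
    triple-median hub filter, hypergeometric over-representation analysis with
    Benjamini-Hochberg correction, tripartite compound-target-pathway network
    degree ranking, and 2^-ddCt relative quantification of qPCR data. Seeded
    synthetic-data generators with machine-readable ground truth replace live
    database and web-tool queries, so every stage is reproducible offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    igraph,
    jsonlite,
    readr,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
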