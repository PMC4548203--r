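Package: padrepo
Title: Network-Based Drug Repositioning for Peripheral Arterial Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies candidate drugs for repositioning in peripheral
    arterial disease (PAD) by intersecting protein-protein interaction
    networks with Gene Ontology derived strategy gene sets (negative
    regulation of angiogenesis, GO:0016525; positive regulation of
    inflammatory response, GO:0050729) and drug-target relations compiled
    from two database dialects (DrugBank-style and PharmGKB-style exports).
    Targets are ranked by network degree, filtered to approved drugs, and
    emitted as candidate tables, bipartite drug-target graphs (SIF and
    GraphML), and literature-evidence query strings. A synthetic-data
    generator with planted druggable-gene ground truth makes every pipeline
    stage testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    xml2
Suggests:
    jsonlite,
    readr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
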