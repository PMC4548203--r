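# padrepo

Network-based drug repositioning for peripheral arterial disease (PAD).

PAD is atherosclerotic occlusion of (chiefly leg) arteries; trials that
tried to force angiogenesis with growth factors such as VEGF have failed,
which motivates two indirect strategies: **inhibit anti-angiogenic genes**
(negative regulation of angiogenesis, GO:0016525) to promote vessel
growth, and **inhibit pro-inflammatory genes** (positive regulation of
inflammatory response, GO:0050729) to damp the chronic inflammation that
drives atherosclerosis. `padrepo` implements this analysis as a tested,
offline pipeline for bioinformaticians evaluating repositioning candidates:

1. parse protein–protein interaction networks (edge list or Cytoscape
   SIF) and rank genes by node degree
   *k(v) = number of interaction partners of v*;
2. load GO-derived strategy gene sets from GMT;
3. normalize drug–gene binary relations from two source dialects —
   DrugBank-style (`drug_drug`, `drug_gene`, `drug_target` rows with the
   five status groups approved / experimental / nutraceutical / illicit /
   withdrawn) and PharmGKB-style (`gene_disease`, `gene_drug`,
   `gene_gene` rows; associated genes, never direct targets);
4. intersect: a **candidate** is a strategy-set gene with at least one
   surviving drug relation after status/kind/source filtering
   (default: direct targets of FDA-approved DrugBank drugs), ranked by
   network degree;
5. export bipartite drug–target graphs (SIF, GraphML, node attributes;
   targets are pink circles, drugs blue squares) and PubMed-style
   evidence query strings such as
   `"(SERPINE1) AND (PAD OR coronary arterial disease)"`.

A synthetic-data generator plants a known druggable-gene subset plus
three decoy classes, so every filter is independently testable without
any database download.

## Worked example

```r
library(padrepo)

fx <- load_pad_fixtures()                    # packaged reference data
anti <- dplyr::filter(fx$gene_sets, set_id == "GO:0016525")
cand <- candidate_table(anti, fx$store, fx$network)
cand
#> # A tibble: 5 × 5
#>   gene     degree in_network drugs     n_drugs
#> * <chr>     <int> <lgl>      <list>      <int>
#> 1 SERPINE1     14 TRUE       <chr [6]>       6
#> 2 CCL2          2 TRUE       <chr [2]>       2
#> 3 NPPB          1 TRUE       <chr [1]>       1
#> 4 NPR1          0 FALSE      <chr [6]>       6
#> 5 PF4           0 FALSE      <chr [1]>       1
```

The five candidate genes are the anti-angiogenic genes with at least one
approved DrugBank drug targeting them; SERPINE1 (plasminogen activator
inhibitor 1) ranks first with degree 14 in the packaged angiome-like
network, and genes absent from that network are retained with degree 0
and `in_network = FALSE`. `glance()` summarizes the table and
`build_bipartite()` turns it into an exportable drug–target graph:

```r
glance(cand)
#> # A tibble: 1 × 6
#>   strategy       set_id     network n_genes n_drugs n_pairs
#> 1 pro_angiogenic GO:0016525 angiome       5      15      16

g <- build_bipartite(cand)
g
#> <pad_bipartite> 5 targets, 15 drugs, 16 edges
head(write_sif(g), 3)
#> alteplase            targets  SERPINE1
#> anistreplase         targets  SERPINE1
#> drotrecogin alfa     targets  SERPINE1
```

`autoplot(g)` draws the two-column bipartite layout;
`write_graphml(g, "graph.graphml")` emits a Cytoscape-loadable file.

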