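---
title: "Methods: network-based drug repositioning for PAD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network-based drug repositioning for PAD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(padrepo)
```

## The model

Peripheral arterial disease (PAD) lacks approved disease-modifying
drugs, and trials that stimulated angiogenesis directly (VEGF, FGF-2)
have failed. `padrepo` operationalizes the complementary idea: activate
a process by inhibiting its negative regulators. Two strategies follow:

* **pro-angiogenic** — inhibit genes annotated to *negative regulation
  of angiogenesis* (GO:0016525, 39 genes);
* **anti-inflammatory** — inhibit genes annotated to *positive
  regulation of inflammatory response* (GO:0050729, 89 genes).

The computation itself is deliberately simple and transparent. Given a
protein–protein interaction network $G = (V, E)$ (simple, undirected),
a strategy gene set $S$, and a set of drug–gene binary relations $R$
with per-drug status groups, the candidate set is

$$ C = \{\, g \in S : \exists\ (d, g) \in R \ \text{with}\ d\
\text{passing the status/kind/source filter} \,\} $$

and candidates are ranked by degree $k(g)$, the number of interaction
partners in $G$. Degree is the only centrality used: it is the measure
the underlying analysis ranks by, and more elaborate scores (diffusion,
proximity) are explicit non-goals. Genes and proteins are identified by
HGNC-style symbols, uppercased on ingest so that variants like `EphA4`
cannot silently miss a match.

## Relation dialects and the approved-drugs filter

Drug–gene relations arrive in two tab-separated dialects that emulate
the exports the analysis consumed:

* **DrugBank-style** (`parse_drugbank_relations()`): rows typed
  `drug_target` / `drug_gene` / `drug_drug`, with a semicolon-joined
  `groups` field over {approved, experimental, nutraceutical, illicit,
  withdrawn}. `drug_target` rows assert direct targeting (kind
  `target`); `drug_gene` rows only association.
* **PharmGKB-style** (`parse_pharmgkb_relations()`): rows typed
  `gene_drug` / `gene_disease` / `gene_gene`. `gene_drug` rows are
  always kind `associated` — this source never asserts direct
  targeting — and the other two row types pass through as opaque side
  tables, which the pipeline stores but never computes on.

The exact column layouts of the original exports are not published, so
the two dialects above are this package's own documented contract;
converters from native DrugBank XML or PharmGKB TSV are out of scope.

`filter_relations()` implements the candidate filter. Its defaults —
`required_groups = "approved"`, `kinds = "target"`,
`sources = "drugbank"` — reproduce the published tables' focus on direct
targets of FDA-approved DrugBank drugs. Three deliberate interpretation
choices, made once and kept:

* *"FDA-approved" means the `approved` token is present.* Withdrawn
  status does **not** exclude a drug by default (drotrecogin alfa is
  listed as approved in the source data despite its later withdrawal);
  pass `forbidden_groups = "withdrawn"` to exclude.
* *Direct targets only by default.* The phrase "drug-gene binary
  relations" is used loosely in the source material; `kinds` is a flag
  so associated-gene links can be admitted explicitly.
* *Drug identity is the whitespace-squeezed lowercase name* for
  deduplication (the printed tables repeat cells like "ginkgo biloba"),
  while the first-seen display spelling is kept for output. PharmGKB
  rows carry no status field, so their drug records are treated as
  approved; they are excluded from default candidates anyway by the
  source and kind filters.

## Networks, degree and ties

Networks are parsed from 2-column edge lists or 3-column Cytoscape SIF
into simple undirected graphs: self-loops are dropped (with a warning),
duplicate and reversed-duplicate edges collapse, and single-token lines
declare isolated nodes. This is the reading of "number of links to a
node" as a distinct-neighbor count, and it keeps the handshake lemma
$\sum_v k(v) = 2|E|$ exact — asserted on every parsed and generated
network in the test suite. Edge direction in input files is ignored
(PPIs are symmetric here). igraph does the degree computation; tests
check it against a direct incidence count.

Ranking (`rank_rows()`) is stable: degree descending, ties broken
alphabetically by symbol. Genes in a strategy set but absent from the
network are kept with degree 0 and an explicit `in_network = FALSE`
flag — the published candidate tables impose no network-membership
requirement, and an absent gene is information, not an error. Absent
degree-0 genes sort after present degree-0 genes. Whether the published
per-target degrees were computed per sub-network or on a merged network
is not stated; the column headers ("degree of target in angiome /
immunome") indicate per-network, which is what this package does.

## Packaged reference data

`load_pad_fixtures()` returns, after MD5 verification:

* the two strategy gene sets (39 + 89 genes; their intersection is
  {CCR2, SERPINE1}), kept verbatim — symbols such as CCL3L3 are not
  remapped to current HGNC, because reproducing the published counts
  outranks nomenclature currency, and GO memberships drift across
  releases anyway;
* a DrugBank-dialect store transcribing the published approved
  drug→target cells plus labelled synthetic decoy rows, and a small
  synthetic PharmGKB-dialect sample;
* the two mechanism-of-action tables with each target's published
  degree (angiome maximum 14 at SERPINE1; immunome maximum 137 at EGFR,
  second distinct value 46 at CCR5);
* a small synthetic angiome-like network (SERPINE1 hub of degree 14).
  The real angiome/immunome/arteriome are supplementary data of a prior
  publication and are not redistributed; any user network in edge-list
  or SIF form can be swapped in.

## The synthetic generator

`generate_synthetic()` emulates only the *relational structure* the
analysis consumes — no disease biology, expression, or pharmacokinetics.
Defaults (chosen once as a realistic desk-scale scenario): 60 genes,
120 edges, 40 drugs with a status mixture of roughly half approved and
the rest mostly experimental (approximating a DrugBank snapshot's
composition), a 20-gene strategy set of which 2 lie outside the network
and 5 are druggable — mirroring the five-gene pro-angiogenic outcome at
the scale of the published analysis. The network model is Erdős–Rényi
$G(n,m)$ by default, with a configuration-model option for heavy-tailed
degree distributions so ranking is exercised on both flat and skewed
degree structure.

Three decoy classes are planted so that each filter is *independently*
falsifiable: (i) approved drugs targeting non-set genes (caught by the
set intersection), (ii) non-approved drugs targeting set genes (caught
by the status filter), (iii) PharmGKB associated relations to set genes
(caught by the kind/source filter). A single integer seed drives all
randomness through one RNG scope, so equal seeds give byte-identical
files. What passing these tests shows is that the pipeline's set
algebra and filters are exact; what they do not show is robustness to
real-data pathologies (symbol aliasing, incomplete curation, literature
bias in interaction networks), which no synthetic benchmark can supply.

## Numerical and degenerate-input choices

* Empty input network, empty store, or empty candidate tables are valid
  and propagate as empty tibbles, never errors.
* Duplicate GMT members and duplicate relation rows collapse with a
  warning or silently (for exact duplicates), respectively; genuinely
  conflicting status groups for one drug id are an error.
* All serializations (edge list, candidate TSV, SIF, GraphML) are
  canonically ordered, so identical inputs give byte-identical output.
* Multi-target drugs appear once per target row (gene-major layout);
  no drug-level aggregation row exists.

## Problem sizes

The packaged analysis runs in seconds. The test suite exercises 100
randomized synthetic scenarios (≈60-node networks) for planted-candidate
recovery against an independent two-loop oracle, plus invariant sweeps
over a further ~15 scenarios; the whole suite completes in well under a
minute on one core. These sizes were chosen to probe the combinatorics
of the filters, not to simulate database scale: the full-snapshot totals
(11,043 DrugBank relations; 3,138 PharmGKB relations; the 1233/5726
angiome) are properties of external databases and are explicitly not
reproduced.

## Known limitations

* Candidate quality is bounded by the curation of the relation tables;
  the package performs no statistical enrichment or significance
  testing, by design.
* Degree ranking inherits study bias in interaction networks:
  well-studied proteins have inflated degree.
* Evidence query strings are generated but never executed; no PubMed,
  DrugBank or PharmGKB client is included.
* Figures are schematic (`autoplot()`); no graph layout optimization is
  attempted.
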