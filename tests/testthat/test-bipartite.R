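pro_angio_candidates <- function() {
  anti <- fixtures$gene_sets[fixtures$gene_sets$set_id == "GO:0016525", ]
  candidate_table(anti, fixtures$store, fixtures$network)
}

test_that("bipartite graph mirrors the candidate table", {
  cand <- pro_angio_candidates()
  g <- build_bipartite(cand)
  expect_equal(sum(g$nodes$role == "target"), 5)
  # drotrecogin alfa hits both PF4 and SERPINE1
  da <- g$edges$gene[g$edges$drug == "drotrecogin alfa"]
  expect_setequal(da, c("PF4", "SERPINE1"))
  # edge count identity: sum of per-row deduplicated drug lists
  expect_equal(nrow(g$edges), sum(cand$n_drugs))

  empty <- build_bipartite(cand[0, ])
  expect_equal(nrow(empty$nodes), 0)
  expect_equal(nrow(empty$edges), 0)
})

test_that("every edge joins one drug node to one target node", {
  sets <- fixtures$gene_sets
  for (id in c("GO:0016525", "GO:0050729")) {
    cand <- candidate_table(sets[sets$set_id == id, ], fixtures$store,
                            fixtures$network)
    g <- build_bipartite(cand)
    role <- setNames(g$nodes$role, g$nodes$node)
    expect_true(all(role[g$edges$drug] == "drug"))
    expect_true(all(role[g$edges$gene] == "target"))
    # no node carries both roles
    expect_equal(anyDuplicated(g$nodes$node), 0L)
  }
})

test_that("the anti-inflammatory graph dominates the pro-angiogenic one", {
  sets <- fixtures$gene_sets
  g1 <- build_bipartite(candidate_table(sets[sets$set_id == "GO:0016525", ],
                                        fixtures$store, fixtures$network))
  g2 <- build_bipartite(candidate_table(sets[sets$set_id == "GO:0050729", ],
                                        fixtures$store, fixtures$network))
  expect_gt(nrow(g2$nodes), nrow(g1$nodes))
  expect_gt(nrow(g2$edges), nrow(g1$edges))
})

test_that("SIF serialization round-trips the edge set", {
  g <- build_bipartite(pro_angio_candidates())
  sif <- write_sif(g)
  expect_equal(length(sif), nrow(g$edges))
  expect_true(all(grepl("\ttargets\t", sif)))
  back <- read_sif(sif)
  expect_equal(dplyr::arrange(back, drug, gene),
               dplyr::arrange(g$edges, drug, gene))

  single <- build_bipartite(tibble::tibble(gene = "G", degree = 1L,
                                           drugs = list("d")))
  expect_equal(write_sif(single), "d\ttargets\tG")
})

test_that("GraphML carries both node roles and the same edges as SIF", {
  g <- build_bipartite(pro_angio_candidates())
  xml <- xml2::read_xml(write_graphml(g))
  ns <- xml2::xml_ns_rename(xml2::xml_ns(xml), d1 = "g")
  nodes <- xml2::xml_find_all(xml, ".//g:node", ns)
  expect_equal(length(nodes), nrow(g$nodes))
  roles <- xml2::xml_text(xml2::xml_find_all(
    xml, ".//g:node/g:data[@key='role']", ns))
  expect_setequal(unique(roles), c("target", "drug"))
  edges <- xml2::xml_find_all(xml, ".//g:edge", ns)
  got <- tibble::tibble(drug = xml2::xml_attr(edges, "source"),
                        gene = xml2::xml_attr(edges, "target"))
  expect_equal(dplyr::arrange(got, drug, gene),
               dplyr::arrange(g$edges, drug, gene))
})

test_that("node-attribute table labels every node with its role", {
  g <- build_bipartite(pro_angio_candidates())
  attrs <- write_node_attributes(g)
  expect_equal(length(attrs), nrow(g$nodes) + 1)
  expect_match(attrs[1], "^node\trole")
})

test_that("evidence queries instantiate the exact keyword templates", {
  expect_equal(evidence_query("SERPINE1"),
               "(SERPINE1) AND (PAD OR coronary arterial disease)")
  expect_equal(evidence_query_drug("carvedilol", "angiogenesis"),
               "(carvedilol) AND angiogenesis")
  expect_equal(evidence_query_drug("maraviroc", "inflammation"),
               "(maraviroc) AND inflammation")
  expect_error(evidence_query(""), "invalid")
  expect_error(evidence_query_drug("", "inflammation"), "non-empty")
})
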