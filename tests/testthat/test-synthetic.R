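test_that("infeasible specs are rejected before generation", {
  expect_error(synthetic_spec(n_genes = 10, n_edges = 100), "infeasible")
  expect_error(synthetic_spec(n_set_genes = 5, n_druggable = 9),
               "infeasible")
  expect_error(synthetic_spec(group_mixture = c(approved = 0.4)),
               "sum to 1")
})

test_that("generation is byte-identical under a fixed seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_synthetic(synthetic_spec(seed = 99), dir = d1)
  generate_synthetic(synthetic_spec(seed = 99), dir = d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
  # a different seed changes at least the relation tables
  d3 <- withr::local_tempdir()
  generate_synthetic(synthetic_spec(seed = 100), dir = d3)
  expect_false(identical(
    unname(tools::md5sum(file.path(d1, "drugbank.tsv"))),
    unname(tools::md5sum(file.path(d3, "drugbank.tsv")))))
})

test_that("emitted files parse cleanly and agree with ground truth", {
  dir <- withr::local_tempdir()
  sc <- generate_synthetic(synthetic_spec(seed = 5), dir = dir)
  net <- read_network(file.path(dir, "network.tsv"), name = "synthetic")
  expect_identical(net$edges, sc$network$edges)
  expect_identical(net$nodes, sc$network$nodes)
  sets <- load_gene_sets(file.path(dir, "gene_sets.gmt"))
  expect_identical(sets, sc$gene_sets)
  db <- parse_drugbank_relations(file.path(dir, "drugbank.tsv"))
  pg <- parse_pharmgkb_relations(file.path(dir, "pharmgkb.tsv"))
  expect_equal(nrow(db$relations), sc$ground_truth$n_relations_drugbank)
  expect_equal(nrow(pg$relations), sc$ground_truth$n_relations_pharmgkb)

  cand <- candidate_table(sets, merge_relation_stores(db, pg), net)
  expect_equal(sort(cand$gene), sc$ground_truth$druggable)
  expect_equal(nrow(cand), sc$ground_truth$n_candidate_rows)
})

test_that("zero planted druggable genes yield an empty candidate table", {
  sc <- generate_synthetic(synthetic_spec(seed = 8, n_druggable = 0))
  st <- merge_relation_stores(
    parse_drugbank_relations(sc$drugbank_lines),
    parse_pharmgkb_relations(sc$pharmgkb_lines))
  cand <- candidate_table(sc$gene_sets, st, sc$network)
  expect_equal(nrow(cand), 0)
})

test_that("the configuration-model mode yields a valid simple network", {
  sc <- generate_synthetic(synthetic_spec(seed = 21,
                                          network_model = "config"))
  dt <- degree_table(sc$network)
  expect_equal(sum(dt$degree), 2L * nrow(sc$network$edges))
  expect_true(all(sc$network$edges$from != sc$network$edges$to))
  expect_equal(anyDuplicated(paste(sc$network$edges$from,
                                   sc$network$edges$to)), 0L)
})

test_that("packaged mechanism tables carry the published degree annotations", {
  mech <- fixtures$mechanisms
  expect_equal(max(mech$pro_angiogenic$degree_angiome), 14)
  degs <- sort(unique(mech$anti_inflammatory$degree_immunome),
               decreasing = TRUE)
  expect_equal(degs[1], 137)
  expect_equal(degs[2], 46)
  # the pro-angiogenic maximum is the SERPINE1 row
  top <- mech$pro_angiogenic[which.max(mech$pro_angiogenic$degree_angiome), ]
  expect_equal(top$target, "SERPINE1")
  expect_equal(top$drug_name, "Alteplase")
})

test_that("fixture loading verifies recorded checksums", {
  expect_silent(invisible(load_pad_fixtures()))
  expect_error(pad_fixture_path("no_such_file.tsv"), "no packaged file")
})
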