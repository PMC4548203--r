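test_that("drugbank dialect parses targets, associated genes and side tables", {
  st <- parse_drugbank_relations(toy_db_lines(c(
    "drug_target\tDB001\tAlteplase\tapproved\tSERPINE1",
    "drug_gene\tDB002\tCarvedilol\tapproved\tSERPINF1",
    "drug_drug\tDB001\tAlteplase\tapproved\tDB002")))
  expect_equal(nrow(st$relations), 2)
  tgt <- st$relations[st$relations$relation_kind == "target", ]
  expect_equal(tgt$drug_name, "Alteplase")
  expect_equal(tgt$gene, "SERPINE1")
  expect_equal(tgt$source, "drugbank")
  expect_equal(nrow(st$side$drug_drug), 1)

  empty <- parse_drugbank_relations(toy_db_lines(character()))
  expect_equal(nrow(empty$relations), 0)
  expect_equal(nrow(empty$drugs), 0)
})

test_that("drugbank dialect rejects bad vocabulary and conflicting groups", {
  expect_error(parse_drugbank_relations(toy_db_lines(
    "drug_banana\tDB1\tX\tapproved\tG1")), "line 2.*relation_type")
  expect_error(parse_drugbank_relations(toy_db_lines(
    "drug_target\tDB1\tX\tshiny\tG1")), "line 2.*group")
  expect_error(parse_drugbank_relations(toy_db_lines(c(
    "drug_target\tDB1\tX\tapproved\tG1",
    "drug_target\tDB1\tX\twithdrawn\tG2"))), "conflicting status groups")
})

test_that("packaged drugbank fixture relation count matches a line-count oracle", {
  path <- pad_fixture_path("drugbank_pad.tsv")
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)][-1]
  f <- strsplit(lines, "\t", fixed = TRUE)
  rel <- f[vapply(f, `[[`, "", 1) %in% c("drug_target", "drug_gene")]
  # hand count: distinct (drug_id, partner, type) rows
  keys <- unique(vapply(rel, function(x) paste(x[1], x[2], x[5]), ""))
  st <- parse_drugbank_relations(path)
  expect_equal(nrow(st$relations), length(keys))
})

test_that("pharmgkb dialect yields only associated relations", {
  st <- parse_pharmgkb_relations(c(
    "relation_type\tgene\tdrug_id\tdrug_name\tpartner",
    "gene_drug\tGENE1\tPA1\tSomeDrug\t",
    "gene_gene\tTNF\t\t\tIL6",
    "gene_disease\tACE\t\t\thypertension"))
  expect_equal(nrow(st$relations), 1)
  expect_equal(st$relations$relation_kind, "associated")
  expect_equal(st$relations$source, "pharmgkb")
  expect_equal(nrow(st$side$gene_gene), 1)
  expect_equal(nrow(st$side$gene_disease), 1)

  # k gene_drug rows -> exactly k associated, 0 target
  k <- 7
  st2 <- parse_pharmgkb_relations(c(
    "relation_type\tgene\tdrug_id\tdrug_name\tpartner",
    sprintf("gene_drug\tG%02d\tPA%02d\tdrug%02d\t", 1:k, 1:k, 1:k)))
  expect_equal(nrow(st2$relations), k)
  expect_equal(sum(st2$relations$relation_kind == "target"), 0)
})

test_that("no pharmgkb-sourced relation is ever a direct target", {
  for (st in list(fixtures$store,
                  parse_pharmgkb_relations(
                    pad_fixture_path("pharmgkb_pad.tsv")))) {
    pg <- st$relations[st$relations$source == "pharmgkb", ]
    expect_true(all(pg$relation_kind == "associated"))
  }
})

test_that("merge preserves per-source provenance and is well-behaved", {
  a <- parse_drugbank_relations(toy_db_lines(
    "drug_target\tDB001\tAlteplase\tapproved\tSERPINE1"))
  b <- parse_pharmgkb_relations(c(
    "relation_type\tgene\tdrug_id\tdrug_name\tpartner",
    "gene_drug\tACE\tPA1\tlisinopril\t"))
  e <- parse_drugbank_relations(toy_db_lines(character()))

  expect_identical(merge_relation_stores(a, e)$relations, a$relations)
  m <- merge_relation_stores(a, b)
  expect_equal(nrow(m$relations), nrow(a$relations) + nrow(b$relations))
  # commutative and associative up to row sets
  sig <- function(s) {
    r <- s$relations
    sort(paste(r$drug_id, r$gene, r$relation_kind, r$source))
  }
  expect_equal(sig(merge_relation_stores(a, b)),
               sig(merge_relation_stores(b, a)))
  expect_equal(sig(merge_relation_stores(merge_relation_stores(a, b), e)),
               sig(merge_relation_stores(a, merge_relation_stores(b, e))))
})

test_that("filter keeps exactly the relations satisfying the predicate", {
  st <- parse_drugbank_relations(toy_db_lines(c(
    "drug_target\tDB001\tGoodol\tapproved\tGENE1",
    "drug_target\tDB002\tTrialin\texperimental\tGENE1",
    "drug_target\tDB003\tPulledol\tapproved;withdrawn\tGENE2")))
  f <- filter_relations(st, required_groups = "approved")
  expect_setequal(f$relations$drug_name, c("Goodol", "Pulledol"))
  # drugs with no surviving relation drop out of the store
  expect_false("DB002" %in% f$drugs$drug_id)

  f2 <- filter_relations(st, required_groups = "approved",
                         forbidden_groups = "withdrawn")
  expect_equal(f2$relations$drug_name, "Goodol")

  expect_error(filter_relations(st, required_groups = "blessed"),
               "unknown drug status group")
  expect_error(filter_relations(st, kinds = "binds"), "unknown relation kind")
})

test_that("filter is idempotent, monotone in requirements, and contained", {
  st <- fixtures$store
  f1 <- filter_relations(st, required_groups = "approved")
  f2 <- filter_relations(f1, required_groups = "approved")
  expect_identical(f1$relations, f2$relations)
  expect_true(nrow(f1$relations) <= nrow(st$relations))
  # stricter requirements shrink the result
  f3 <- filter_relations(st, required_groups = c("approved", "withdrawn"))
  expect_true(nrow(f3$relations) <= nrow(f1$relations))
  # forbidding a group never grows the result
  f4 <- filter_relations(st, required_groups = "approved",
                         forbidden_groups = "experimental")
  expect_true(nrow(f4$relations) <= nrow(f1$relations))
})

test_that("planted approved-target relations are counted exactly after filtering", {
  sc <- generate_synthetic(synthetic_spec(
    seed = 42, n_drugs = 30, n_druggable = 12, n_set_genes = 25,
    n_decoy_approved_nonset = 0, n_decoy_nonapproved_set = 40,
    n_decoy_pharmgkb_set = 20))
  st <- merge_relation_stores(
    parse_drugbank_relations(sc$drugbank_lines),
    parse_pharmgkb_relations(sc$pharmgkb_lines))
  f <- filter_relations(st, required_groups = "approved",
                        kinds = "target", sources = "drugbank")
  expect_setequal(unique(f$relations$gene), sc$ground_truth$druggable)
})
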