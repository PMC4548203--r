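#' Specification for a synthetic repositioning scenario
#'
#' Describes a fully synthetic stand-in for the analysis inputs — an
#' interaction network, a strategy gene set, and drug-relation tables in
#' both source dialects — with planted ground truth: exactly
#' `n_druggable` genes of the strategy set receive at least one approved
#' DrugBank target relation, so the candidate table recoverable from the
#' generated files is known by construction. Three decoy classes are
#' planted so that each status/kind/source filter is independently
#' exercised: approved drugs targeting non-set genes, non-approved drugs
#' targeting set genes, and PharmGKB associated relations to set genes.
#'
#' @param seed Integer seed governing all randomness.
#' @param n_genes Number of network genes.
#' @param n_edges Number of network edges (must fit a simple graph).
#' @param n_drugs Number of drugs in the DrugBank-dialect table.
#' @param group_mixture Named proportions over the five status groups
#'   (must sum to 1). The defaults approximate the status composition of a
#'   DrugBank snapshot: roughly half approved, the rest mostly
#'   experimental.
#' @param n_set_genes Size of the planted strategy gene set.
#' @param n_set_outside How many of the set genes lie outside the network
#'   (they exercise the degree-0 absent-flag path).
#' @param n_druggable Number of set genes given >= 1 approved DrugBank
#'   target relation (the planted candidates).
#' @param n_decoy_approved_nonset,n_decoy_nonapproved_set,n_decoy_pharmgkb_set
#'   Sizes of the three decoy classes.
#' @param network_model `"gnm"` for an Erdos-Renyi G(n, m) graph or
#'   `"config"` for a configuration-model graph with heavy-tailed degrees
#'   (simplified: multi-edges and loops removed).
#' @return A validated `synthetic_spec` list.
#' @export
synthetic_spec <- function(seed = 1L,
                           n_genes = 60L,
                           n_edges = 120L,
                           n_drugs = 40L,
                           group_mixture = c(approved = 0.5,
                                             experimental = 0.3,
                                             nutraceutical = 0.05,
                                             illicit = 0.05,
                                             withdrawn = 0.1),
                           n_set_genes = 20L,
                           n_set_outside = 2L,
                           n_druggable = 5L,
                           n_decoy_approved_nonset = 10L,
                           n_decoy_nonapproved_set = 8L,
                           n_decoy_pharmgkb_set = 6L,
                           network_model = c("gnm", "config")) {
  network_model <- match.arg(network_model)
  spec <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
               n_edges = as.integer(n_edges), n_drugs = as.integer(n_drugs),
               group_mixture = group_mixture,
               n_set_genes = as.integer(n_set_genes),
               n_set_outside = as.integer(n_set_outside),
               n_druggable = as.integer(n_druggable),
               n_decoy_approved_nonset = as.integer(n_decoy_approved_nonset),
               n_decoy_nonapproved_set = as.integer(n_decoy_nonapproved_set),
               n_decoy_pharmgkb_set = as.integer(n_decoy_pharmgkb_set),
               network_model = network_model)
  max_edges <- spec$n_genes * (spec$n_genes - 1) / 2
  if (spec$n_edges > max_edges) {
    abort(sprintf("infeasible spec: %d edges exceed the %d possible in a simple graph on %d nodes",
                  spec$n_edges, max_edges, spec$n_genes))
  }
  if (spec$n_set_outside > spec$n_set_genes ||
      spec$n_druggable > spec$n_set_genes ||
      spec$n_set_genes - spec$n_set_outside > spec$n_genes) {
    abort("infeasible spec: require n_set_outside, n_druggable <= n_set_genes and in-network set genes <= n_genes")
  }
  if (abs(sum(group_mixture) - 1) > 1e-8 ||
      !all(names(group_mixture) %in% DRUG_GROUPS)) {
    abort("group_mixture must be named by the five status groups and sum to 1")
  }
  structure(spec, class = "synthetic_spec")
}

#' Generate a synthetic repositioning scenario
#'
#' Emits the exact plain-text formats consumed by the parsers — network
#' edge list, gene-set GMT, DrugBank-dialect TSV, PharmGKB-dialect TSV —
#' plus a key-value ground-truth file, all deterministically from
#' `spec$seed` (same seed, byte-identical files).
#'
#' @param spec A [synthetic_spec()].
#' @param dir Output directory (created if needed); `NULL` keeps
#'   everything in memory only.
#' @return A list with the parsed in-memory objects (`network`,
#'   `gene_sets`, `drugbank_lines`, `pharmgkb_lines`) the `ground_truth`
#'   (planted druggable genes, per-source relation counts, expected
#'   candidate row count), and `paths` when `dir` is given.
#' @examples
#' sc <- generate_synthetic(synthetic_spec(seed = 7))
#' sc$ground_truth$druggable
#' @export
generate_synthetic <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  # sample() from a length-1 numeric vector would expand to 1:x
  resample <- function(x, size, replace = FALSE) {
    x[sample.int(length(x), size, replace = replace)]
  }
  withr::with_seed(spec$seed, {
    genes <- sprintf("G%03d", seq_len(spec$n_genes))
    graph <- if (spec$network_model == "gnm") {
      igraph::sample_gnm(spec$n_genes, spec$n_edges)
    } else {
      degs <- pmin(sample(2:8, spec$n_genes, replace = TRUE,
                          prob = 1 / (2:8)^2) +
                     stats::rpois(spec$n_genes, 1), spec$n_genes - 1)
      if (sum(degs) %% 2 == 1) degs[1] <- degs[1] + 1
      igraph::simplify(igraph::sample_degseq(degs, method = "configuration"))
    }
    el <- igraph::as_edgelist(graph)
    network <- pad_network(
      tibble::tibble(from = genes[el[, 1]], to = genes[el[, 2]]),
      nodes = genes, name = "synthetic")

    outside <- if (spec$n_set_outside > 0) {
      sprintf("X%03d", seq_len(spec$n_set_outside))
    } else character()
    set_genes <- sort(c(resample(genes, spec$n_set_genes - spec$n_set_outside),
                        outside))
    druggable <- sort(resample(set_genes, spec$n_druggable))
    nonset <- setdiff(genes, set_genes)

    status <- sample(names(spec$group_mixture), spec$n_drugs, replace = TRUE,
                     prob = spec$group_mixture)
    # the planted relations need approved drugs and the class-ii decoys
    # non-approved ones; guarantee at least one of each
    status[1] <- "approved"
    status[2] <- "experimental"
    drugs <- tibble::tibble(
      drug_id = sprintf("SD%04d", seq_len(spec$n_drugs)),
      drug_name = sprintf("syndrug%03d", seq_len(spec$n_drugs)),
      groups = status)
    approved_ids <- which(status == "approved")
    other_ids <- which(status != "approved")

    planted <- tibble::tibble(
      relation_type = "drug_target",
      idx = resample(approved_ids, spec$n_druggable, replace = TRUE),
      partner = druggable)
    decoy_i <- tibble::tibble(     # approved drugs -> non-set genes
      relation_type = "drug_target",
      idx = resample(approved_ids, spec$n_decoy_approved_nonset,
                     replace = TRUE),
      partner = resample(nonset, spec$n_decoy_approved_nonset,
                         replace = TRUE))
    decoy_ii <- tibble::tibble(    # non-approved drugs -> set genes
      relation_type = "drug_target",
      idx = resample(other_ids, spec$n_decoy_nonapproved_set, replace = TRUE),
      partner = resample(set_genes, spec$n_decoy_nonapproved_set,
                         replace = TRUE))
    db_rel <- dplyr::distinct(
      dplyr::bind_rows(planted, decoy_i, decoy_ii))
    db_lines <- c(
      paste("relation_type", "drug_id", "drug_name", "groups", "partner",
            sep = "\t"),
      sprintf("%s\t%s\t%s\t%s\t%s", db_rel$relation_type,
              drugs$drug_id[db_rel$idx], drugs$drug_name[db_rel$idx],
              drugs$groups[db_rel$idx], db_rel$partner))

    pg_genes <- resample(set_genes, spec$n_decoy_pharmgkb_set, replace = TRUE)
    pg_rel <- dplyr::distinct(tibble::tibble(
      gene = pg_genes,
      drug_id = sprintf("SP%04d", seq_along(pg_genes)),
      drug_name = sprintf("synassoc%03d", seq_along(pg_genes))))
    pg_lines <- c(
      paste("relation_type", "gene", "drug_id", "drug_name", "partner",
            sep = "\t"),
      sprintf("gene_drug\t%s\t%s\t%s\t", pg_rel$gene, pg_rel$drug_id,
              pg_rel$drug_name))

    gmt_line <- paste(c("SYN:SET1", "planted strategy set", set_genes),
                      collapse = "\t")
    ground_truth <- list(
      druggable = druggable,
      n_relations_drugbank = nrow(db_rel),
      n_relations_pharmgkb = nrow(pg_rel),
      n_candidate_rows = length(druggable)
    )
  })
  out <- list(network = network,
              gene_sets = load_gene_sets(gmt_line),
              drugbank_lines = db_lines,
              pharmgkb_lines = pg_lines,
              ground_truth = ground_truth)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- file.path(dir, c(network = "network.tsv",
                              gene_sets = "gene_sets.gmt",
                              drugbank = "drugbank.tsv",
                              pharmgkb = "pharmgkb.tsv",
                              ground_truth = "ground_truth.tsv"))
    names(paths) <- c("network", "gene_sets", "drugbank", "pharmgkb",
                      "ground_truth")
    write_network(network, paths[["network"]])
    writeLines(gmt_line, paths[["gene_sets"]])
    writeLines(db_lines, paths[["drugbank"]])
    writeLines(pg_lines, paths[["pharmgkb"]])
    writeLines(c(
      paste0("druggable\t", paste(ground_truth$druggable, collapse = ";")),
      paste0("n_relations_drugbank\t", ground_truth$n_relations_drugbank),
      paste0("n_relations_pharmgkb\t", ground_truth$n_relations_pharmgkb),
      paste0("n_candidate_rows\t", ground_truth$n_candidate_rows)),
      paths[["ground_truth"]])
    out$paths <- paths
  }
  out
}
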