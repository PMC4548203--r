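#' Per-network target table (gene -> drugs, ranked by degree)
#'
#' Matches the genes of an interaction network against the drug-gene
#' relations of a store and emits one row per network gene with at least
#' one relation; genes without any drug-gene relation are skipped. Multiple
#' drugs hitting the same target are listed in that target's single row,
#' split by source, deduplicated and alphabetized. Rows are ranked by
#' network degree (descending, ties alphabetical).
#'
#' @param network A [pad_network()].
#' @param store A `pad_relations` store (pre-filter it with
#'   [filter_relations()] to restrict status/kind/source).
#' @return A tibble with columns `gene`, `degree`, `in_network` (all
#'   `TRUE` here), `drugs_drugbank`, `drugs_pharmgkb` (list columns of
#'   drug names) and `network_name`.
#' @export
target_table <- function(network, store) {
  stopifnot(inherits(network, "pad_network"),
            inherits(store, "pad_relations"))
  rel <- store$relations[store$relations$gene %in% network$nodes, ,
                         drop = FALSE]
  rows <- gene_drug_rows(unique(rel$gene), rel, network)
  rows$network_name <- rep(network$name, nrow(rows))
  rank_rows(rows)
}

# Shared row builder: one row per gene with per-source deduplicated,
# alphabetized drug-name lists and the gene's degree/absent flag.
gene_drug_rows <- function(genes, rel, network) {
  deg <- network_degree(network, if (length(genes)) genes else NULL)
  if (!length(genes)) deg <- deg[0, ]
  drugs_for <- function(g, src) {
    nm <- rel$drug_name[rel$gene == g & rel$source == src]
    sort(unique(nm[!duplicated(normalize_drug_name(nm))]))
  }
  tibble::tibble(
    gene = deg$gene,
    degree = deg$degree,
    in_network = deg$in_network,
    drugs_drugbank = purrr::map(deg$gene, drugs_for, src = "drugbank"),
    drugs_pharmgkb = purrr::map(deg$gene, drugs_for, src = "pharmgkb")
  )
}

#' Rank target rows by network degree
#'
#' Stable sort, degree descending; ties broken alphabetically by gene
#' symbol; genes flagged absent from the network (degree 0 with
#' `in_network = FALSE`) sort after present degree-0 genes. The output is a
#' permutation of the input rows.
#'
#' @param rows A tibble with columns `gene`, `degree` and (optionally)
#'   `in_network`.
#' @return The same tibble, reordered.
#' @export
rank_rows <- function(rows) {
  stopifnot(all(c("gene", "degree") %in% names(rows)))
  in_net <- if ("in_network" %in% names(rows)) rows$in_network else
    rep(TRUE, nrow(rows))
  rows[order(-rows$degree, !in_net, rows$gene, method = "radix"), ,
       drop = FALSE]
}

#' Strategy candidate table
#'
#' The core repositioning step: for one strategy gene set (anti-angiogenic
#' genes whose inhibition is pro-angiogenic, or pro-inflammatory genes
#' whose inhibition is anti-inflammatory), list every member gene targeted
#' by at least one drug surviving the status/kind/source filter, with its
#' network degree and its deduplicated, alphabetized drug list, ranked by
#' degree. Genes of the set absent from the network are retained with
#' degree 0 and `in_network = FALSE`.
#'
#' @param gene_set A single gene set: tibble rows from [load_gene_sets()]
#'   (one `set_id`) or a character vector of symbols.
#' @param store A `pad_relations` store (unfiltered; filtering is applied
#'   here).
#' @param network A [pad_network()] providing degrees.
#' @param approved_only If `TRUE` (default) only drugs whose status groups
#'   include `approved` are considered.
#' @param sources Relation sources to use; default `"drugbank"` as in the
#'   published candidate tables.
#' @param kinds Relation kinds to use; default `"target"` (direct targets
#'   only), set to `c("target", "associated")` to also admit
#'   associated-gene links.
#' @param strategy Strategy label stored on the result; defaults to
#'   `"pro_angiogenic"` for GO:0016525, `"anti_inflammatory"` for
#'   GO:0050729, otherwise `"custom"`.
#' @return A tibble of class `pad_candidates` with columns `gene`,
#'   `degree`, `in_network`, `drugs` (list column) and `n_drugs`, plus
#'   attributes `strategy`, `set_id` and `network_name`.
#' @examples
#' fx <- load_pad_fixtures()
#' cand <- candidate_table(
#'   dplyr::filter(fx$gene_sets, set_id == "GO:0016525"),
#'   fx$store, fx$network)
#' cand$gene
#' @export
candidate_table <- function(gene_set, store, network,
                            approved_only = TRUE,
                            sources = "drugbank",
                            kinds = "target",
                            strategy = NULL) {
  members <- set_members(gene_set)
  if (!length(members)) abort("gene_set has no members")
  set_id <- if (is.data.frame(gene_set)) unique(gene_set$set_id) else "custom"
  if (length(set_id) != 1) {
    abort("gene_set must contain a single set_id; filter first")
  }
  strategy <- strategy %||% switch(set_id,
                                   "GO:0016525" = "pro_angiogenic",
                                   "GO:0050729" = "anti_inflammatory",
                                   "custom")
  filtered <- filter_relations(
    store,
    required_groups = if (approved_only) "approved" else character(),
    kinds = kinds, sources = sources)
  rel <- filtered$relations[filtered$relations$gene %in% members, ,
                            drop = FALSE]
  rows <- gene_drug_rows(unique(rel$gene), rel, network)
  rows$drugs <- purrr::map2(rows$drugs_drugbank, rows$drugs_pharmgkb,
                            function(a, b) sort(unique(c(a, b))))
  rows$n_drugs <- lengths(rows$drugs)
  rows <- rows[, c("gene", "degree", "in_network", "drugs", "n_drugs")]
  out <- rank_rows(rows)
  structure(out,
            class = c("pad_candidates", class(out)),
            strategy = strategy, set_id = set_id,
            network_name = network$name)
}

#' Summarize both strategy candidate tables
#'
#' @param pro_angiogenic,anti_inflammatory `pad_candidates` tables from
#'   [candidate_table()].
#' @return A list of class `pad_strategy_report` with per-strategy gene and
#'   distinct-drug counts and the genes shared between the two strategies.
#' @export
strategy_report <- function(pro_angiogenic, anti_inflammatory) {
  count_one <- function(x) {
    list(n_genes = nrow(x),
         n_drugs = length(unique(normalize_drug_name(
           unlist(x$drugs, use.names = FALSE)))))
  }
  structure(list(
    pro_angiogenic = count_one(pro_angiogenic),
    anti_inflammatory = count_one(anti_inflammatory),
    shared_genes = sort(intersect(pro_angiogenic$gene,
                                  anti_inflammatory$gene))
  ), class = "pad_strategy_report")
}

#' @export
print.pad_strategy_report <- function(x, ...) {
  cat(sprintf("pro-angiogenic: %d genes, %d drugs\n",
              x$pro_angiogenic$n_genes, x$pro_angiogenic$n_drugs))
  cat(sprintf("anti-inflammatory: %d genes, %d drugs\n",
              x$anti_inflammatory$n_genes, x$anti_inflammatory$n_drugs))
  cat("shared genes:", paste(x$shared_genes, collapse = ", "), "\n")
  invisible(x)
}

#' @method tidy pad_strategy_report
#' @export
tidy.pad_strategy_report <- function(x, ...) {
  tibble::tibble(
    strategy = c("pro_angiogenic", "anti_inflammatory"),
    n_genes = c(x$pro_angiogenic$n_genes, x$anti_inflammatory$n_genes),
    n_drugs = c(x$pro_angiogenic$n_drugs, x$anti_inflammatory$n_drugs),
    n_shared_genes = length(x$shared_genes)
  )
}

#' @method tidy pad_candidates
#' @export
tidy.pad_candidates <- function(x, ...) {
  tidyr::unnest(
    tibble::tibble(gene = x$gene, degree = x$degree,
                   in_network = x$in_network, drug = x$drugs),
    "drug")
}

#' @method glance pad_candidates
#' @export
glance.pad_candidates <- function(x, ...) {
  tibble::tibble(
    strategy = attr(x, "strategy"),
    set_id = attr(x, "set_id"),
    network = attr(x, "network_name"),
    n_genes = nrow(x),
    n_drugs = length(unique(normalize_drug_name(
      unlist(x$drugs, use.names = FALSE)))),
    n_pairs = sum(x$n_drugs)
  )
}

# Semicolon-joined serialization shared by the table writers; byte-stable
# given identical inputs.
join_drugs <- function(x) vapply(x, paste, "", collapse = "; ")

#' Write a target or candidate table as TSV
#'
#' List columns of drug names are serialized semicolon-joined and
#' alphabetized, mirroring the published table layout. Output is
#' deterministic: identical inputs give byte-identical files.
#'
#' @param x A tibble from [target_table()] or [candidate_table()].
#' @param path Output file path, or `NULL` to return the lines.
#' @return The serialized lines, invisibly when `path` is given.
#' @export
write_candidate_table <- function(x, path = NULL) {
  out <- as.data.frame(x)
  for (col in intersect(c("drugs", "drugs_drugbank", "drugs_pharmgkb"),
                        names(out))) {
    out[[col]] <- join_drugs(out[[col]])
  }
  lines <- c(paste(names(out), collapse = "\t"),
             do.call(paste, c(lapply(out, as.character), sep = "\t")))
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}
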