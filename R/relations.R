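DRUG_GROUPS <- c("approved", "experimental", "nutraceutical", "illicit",
                 "withdrawn")
RELATION_KINDS <- c("target", "associated")
RELATION_SOURCES <- c("drugbank", "pharmgkb")

new_relation_store <- function(drugs, relations, side) {
  structure(list(drugs = drugs, relations = relations, side = side),
            class = "pad_relations")
}

empty_side <- function() {
  list(
    drug_drug = tibble::tibble(drug_id = character(), drug_name = character(),
                               partner = character(), source = character()),
    gene_gene = tibble::tibble(gene = character(), partner = character(),
                               source = character()),
    gene_disease = tibble::tibble(gene = character(), partner = character(),
                                  source = character())
  )
}

#' @export
print.pad_relations <- function(x, ...) {
  cat(sprintf(paste0("<pad_relations> %d drugs, %d drug-gene relations ",
                     "(%d target / %d associated)\n"),
              nrow(x$drugs), nrow(x$relations),
              sum(x$relations$relation_kind == "target"),
              sum(x$relations$relation_kind == "associated")))
  invisible(x)
}

read_dialect_tsv <- function(lines, required_cols, dialect) {
  if (length(lines) == 1 && file.exists(lines)) {
    lines <- readLines(lines, warn = FALSE)
  }
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (!any(keep)) abort(sprintf("%s input has no header row", dialect))
  header <- strsplit(lines[idx[1]], "\t", fixed = TRUE)[[1]]
  missing_cols <- setdiff(required_cols, header)
  if (length(missing_cols)) {
    abort(sprintf("%s header lacks column(s): %s", dialect,
                  paste(missing_cols, collapse = ", ")))
  }
  body_idx <- idx[-1]
  rows <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  tab <- purrr::map_dfr(seq_along(rows), function(i) {
    f <- rows[[i]]
    length(f) <- length(header)
    f[is.na(f)] <- ""
    setNames(as.list(f), header)
  })
  tab$.line <- body_idx
  tab
}

parse_groups <- function(groups, lines) {
  toks <- strsplit(groups, ";", fixed = TRUE)
  toks <- lapply(toks, function(g) tolower(trimws(g)))
  bad <- vapply(toks, function(g) length(g) == 0 || any(!g %in% DRUG_GROUPS),
                logical(1))
  if (any(bad)) {
    abort(sprintf("line %d: unknown drug status group %s (allowed: %s)",
                  lines[which(bad)[1]], sQuote(groups[which(bad)[1]]),
                  paste(DRUG_GROUPS, collapse = ", ")))
  }
  lapply(toks, unique)
}

# Collapse per-row drug mentions into one DrugRecord per id, erroring on
# conflicting status groups for the same (id, name) and deduplicating
# case-insensitively on the display name.
build_drug_table <- function(drug_id, drug_name, groups, lines, source) {
  tab <- tibble::tibble(
    drug_id = drug_id,
    drug_name = trimws(drug_name),
    name_key = normalize_drug_name(drug_name),
    group_key = vapply(groups, function(g) paste(sort(g), collapse = ";"), ""),
    groups = groups, .line = lines
  )
  if (any(!nzchar(tab$drug_id)) || any(!nzchar(tab$name_key))) {
    abort(sprintf("line %d: drug rows need non-empty drug_id and drug_name",
                  tab$.line[which(!nzchar(tab$drug_id) |
                                    !nzchar(tab$name_key))[1]]))
  }
  conflict <- dplyr::summarise(
    dplyr::group_by(tab, .data$drug_id, .data$name_key),
    n_group_defs = dplyr::n_distinct(.data$group_key), .groups = "drop")
  conflict <- conflict[conflict$n_group_defs > 1, ]
  if (nrow(conflict)) {
    abort(sprintf("drug %s: conflicting status groups across rows",
                  sQuote(conflict$drug_id[1])))
  }
  out <- dplyr::slice_head(dplyr::group_by(tab, .data$drug_id, .data$name_key),
                           n = 1)
  out <- dplyr::ungroup(out)
  tibble::tibble(drug_id = out$drug_id, drug_name = out$drug_name,
                 groups = out$groups, source = source)
}

#' Parse DrugBank-dialect drug relations
#'
#' Reads the tab-separated DrugBank-style export with header columns
#' `relation_type`, `drug_id`, `drug_name`, `groups`, `partner`.
#' `relation_type` is one of `drug_target`, `drug_gene`, `drug_drug`;
#' `groups` is a semicolon-joined subset of the five drug status words
#' (approved, experimental, nutraceutical, illicit, withdrawn). Rows of
#' type `drug_target` become relations of kind `"target"`, `drug_gene`
#' rows become kind `"associated"`, and `drug_drug` rows are kept in an
#' untyped side table. All output carries `source = "drugbank"`.
#'
#' @param lines Character vector of TSV lines, or a path to a TSV file.
#' @return A `pad_relations` store: list with `drugs` (tibble of drug
#'   records with list column `groups`), `relations` (tibble with columns
#'   `drug_id`, `drug_name`, `gene`, `relation_kind`, `source`) and `side`
#'   (untyped pass-through tables).
#' @export
parse_drugbank_relations <- function(lines) {
  tab <- read_dialect_tsv(
    lines, c("relation_type", "drug_id", "drug_name", "groups", "partner"),
    "drugbank dialect")
  if (nrow(tab) == 0) {
    return(new_relation_store(
      build_drug_table(character(), character(), list(), integer(),
                       "drugbank"),
      tibble::tibble(drug_id = character(), drug_name = character(),
                     gene = character(), relation_kind = character(),
                     source = character()),
      empty_side()))
  }
  known <- c("drug_target", "drug_gene", "drug_drug")
  bad <- !tab$relation_type %in% known
  if (any(bad)) {
    abort(sprintf("line %d: unknown relation_type %s (allowed: %s)",
                  tab$.line[which(bad)[1]],
                  sQuote(tab$relation_type[which(bad)[1]]),
                  paste(known, collapse = ", ")))
  }
  groups <- parse_groups(tab$groups, tab$.line)
  drugs <- build_drug_table(tab$drug_id, tab$drug_name, groups, tab$.line,
                            "drugbank")
  rel_rows <- tab$relation_type %in% c("drug_target", "drug_gene")
  relations <- tibble::tibble(
    drug_id = tab$drug_id[rel_rows],
    drug_name = trimws(tab$drug_name[rel_rows]),
    gene = canonicalize_symbol(tab$partner[rel_rows], "target gene"),
    relation_kind = ifelse(tab$relation_type[rel_rows] == "drug_target",
                           "target", "associated"),
    source = "drugbank"
  )
  relations <- dplyr::distinct(relations, .data$drug_id, .data$gene,
                               .data$relation_kind, .data$source,
                               .keep_all = TRUE)
  side <- empty_side()
  dd <- tab[tab$relation_type == "drug_drug", ]
  side$drug_drug <- tibble::tibble(drug_id = dd$drug_id,
                                   drug_name = trimws(dd$drug_name),
                                   partner = dd$partner,
                                   source = "drugbank")
  new_relation_store(drugs, relations, side)
}

#' Parse PharmGKB-dialect gene relations
#'
#' Reads the tab-separated PharmGKB-style export with header columns
#' `relation_type`, `gene`, `drug_id`, `drug_name`, `partner`.
#' `relation_type` is one of `gene_drug`, `gene_disease`, `gene_gene`.
#' Only `gene_drug` rows produce drug-gene relations, always of kind
#' `"associated"` (this dialect asserts association, never direct
#' targeting); the other rows pass through to untyped side tables. Drug
#' status groups are not carried by this dialect, so every drug record is
#' marked `approved` unless filtered otherwise downstream.
#'
#' @param lines Character vector of TSV lines, or a path to a TSV file.
#' @return A `pad_relations` store; see [parse_drugbank_relations()].
#' @export
parse_pharmgkb_relations <- function(lines) {
  tab <- read_dialect_tsv(
    lines, c("relation_type", "gene", "drug_id", "drug_name", "partner"),
    "pharmgkb dialect")
  known <- c("gene_drug", "gene_disease", "gene_gene")
  if (nrow(tab) > 0) {
    bad <- !tab$relation_type %in% known
    if (any(bad)) {
      abort(sprintf("line %d: unknown relation_type %s (allowed: %s)",
                    tab$.line[which(bad)[1]],
                    sQuote(tab$relation_type[which(bad)[1]]),
                    paste(known, collapse = ", ")))
    }
  }
  gd <- tab[tab$relation_type == "gene_drug", , drop = FALSE]
  drugs <- build_drug_table(gd$drug_id, gd$drug_name,
                            rep(list("approved"), nrow(gd)),
                            gd$.line, "pharmgkb")
  relations <- tibble::tibble(
    drug_id = gd$drug_id,
    drug_name = trimws(gd$drug_name),
    gene = if (nrow(gd)) canonicalize_symbol(gd$gene) else character(),
    relation_kind = rep("associated", nrow(gd)),
    source = rep("pharmgkb", nrow(gd))
  )
  relations <- dplyr::distinct(relations, .data$drug_id, .data$gene,
                               .data$relation_kind, .data$source,
                               .keep_all = TRUE)
  side <- empty_side()
  gg <- tab[tab$relation_type == "gene_gene", , drop = FALSE]
  gdis <- tab[tab$relation_type == "gene_disease", , drop = FALSE]
  side$gene_gene <- tibble::tibble(
    gene = if (nrow(gg)) canonicalize_symbol(gg$gene) else character(),
    partner = gg$partner, source = rep("pharmgkb", nrow(gg)))
  side$gene_disease <- tibble::tibble(
    gene = if (nrow(gdis)) canonicalize_symbol(gdis$gene) else character(),
    partner = gdis$partner, source = rep("pharmgkb", nrow(gdis)))
  new_relation_store(drugs, relations, side)
}

#' Merge relation stores
#'
#' Union of drugs, relations and side tables with per-source provenance
#' preserved. Drug ids are source-scoped, so no cross-source collision
#' handling is attempted; exact duplicate rows collapse.
#'
#' @param ... `pad_relations` stores.
#' @return A merged `pad_relations` store.
#' @export
merge_relation_stores <- function(...) {
  stores <- list(...)
  stopifnot(length(stores) >= 1,
            all(vapply(stores, inherits, logical(1), "pad_relations")))
  drugs <- dplyr::bind_rows(lapply(stores, `[[`, "drugs"))
  drugs <- dplyr::slice_head(
    dplyr::group_by(drugs, .data$drug_id, .data$source,
                    normalize_drug_name(.data$drug_name)), n = 1)
  drugs <- dplyr::ungroup(drugs)[, c("drug_id", "drug_name", "groups",
                                     "source")]
  relations <- dplyr::distinct(
    dplyr::bind_rows(lapply(stores, `[[`, "relations")),
    .data$drug_id, .data$gene, .data$relation_kind, .data$source,
    .keep_all = TRUE)
  side <- empty_side()
  for (nm in names(side)) {
    side[[nm]] <- dplyr::distinct(
      dplyr::bind_rows(lapply(stores, function(s) s$side[[nm]])))
  }
  new_relation_store(drugs, relations, side)
}

#' Filter drug-gene relations by status, kind and source
#'
#' Keeps a relation iff its drug carries every group in `required_groups`,
#' none in `forbidden_groups`, and the relation's kind and source fall in
#' the allowed sets. Drugs left with no surviving relation are dropped from
#' the filtered store. The defaults reproduce the approved-drugs focus of
#' the repositioning analysis: direct DrugBank targets of approved drugs.
#'
#' @param store A `pad_relations` store.
#' @param required_groups,forbidden_groups Subsets of
#'   `c("approved", "experimental", "nutraceutical", "illicit", "withdrawn")`.
#' @param kinds Subset of `c("target", "associated")`.
#' @param sources Subset of `c("drugbank", "pharmgkb")`.
#' @return The filtered `pad_relations` store (side tables pass through).
#' @export
filter_relations <- function(store,
                             required_groups = "approved",
                             forbidden_groups = character(),
                             kinds = "target",
                             sources = "drugbank") {
  stopifnot(inherits(store, "pad_relations"))
  check_vocab <- function(x, allowed, what) {
    bad <- setdiff(x, allowed)
    if (length(bad)) {
      abort(sprintf("unknown %s token(s): %s (allowed: %s)", what,
                    paste(sQuote(bad), collapse = ", "),
                    paste(allowed, collapse = ", ")))
    }
  }
  check_vocab(required_groups, DRUG_GROUPS, "drug status group")
  check_vocab(forbidden_groups, DRUG_GROUPS, "drug status group")
  check_vocab(kinds, RELATION_KINDS, "relation kind")
  check_vocab(sources, RELATION_SOURCES, "relation source")

  ok_drug <- vapply(store$drugs$groups, function(g) {
    all(required_groups %in% g) && !any(forbidden_groups %in% g)
  }, logical(1))
  keyed <- paste(store$drugs$drug_id, store$drugs$source)
  ok_ids <- keyed[ok_drug]
  rel <- store$relations
  keep <- paste(rel$drug_id, rel$source) %in% ok_ids &
    rel$relation_kind %in% kinds & rel$source %in% sources
  rel <- rel[keep, , drop = FALSE]
  drugs <- store$drugs[keyed %in% paste(rel$drug_id, rel$source), ,
                       drop = FALSE]
  new_relation_store(drugs, rel, store$side)
}

#' @method tidy pad_relations
#' @export
tidy.pad_relations <- function(x, ...) x$relations

#' @method glance pad_relations
#' @export
glance.pad_relations <- function(x, ...) {
  tibble::tibble(
    n_drugs = nrow(x$drugs),
    n_relations = nrow(x$relations),
    n_target = sum(x$relations$relation_kind == "target"),
    n_associated = sum(x$relations$relation_kind == "associated"),
    n_drugbank = sum(x$relations$source == "drugbank"),
    n_pharmgkb = sum(x$relations$source == "pharmgkb")
  )
}
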