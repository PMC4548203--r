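#' Parse gene sets from GMT text
#'
#' Reads Broad-style GMT: one set per line, tab-separated as
#' `set_id<TAB>description<TAB>gene1<TAB>gene2...`. Member symbols are
#' canonicalized to uppercase; duplicates within a line collapse with a
#' warning. The result is tidy: one row per (set, gene) pair.
#'
#' @param lines Character vector of GMT lines, or a single path to a GMT
#'   file (detected by file existence).
#' @return A tibble with columns `set_id`, `label`, `gene`.
#' @examples
#' load_gene_sets("GO:X\tdemo set\tTHBS1\tSERPINE1")
#' @export
load_gene_sets <- function(lines) {
  if (length(lines) == 1 && file.exists(lines)) {
    lines <- readLines(lines, warn = FALSE)
  }
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  short <- lengths(fields) < 3
  if (any(short)) {
    abort(sprintf("malformed GMT line %d: expected >= 3 tab-separated fields",
                  idx[which(short)[1]]))
  }
  sets <- purrr::map_dfr(fields, function(f) {
    members <- canonicalize_symbol(f[-(1:2)])
    if (anyDuplicated(members)) {
      warn(sprintf("gene set %s: collapsing %d duplicate member symbol(s)",
                   f[[1]], sum(duplicated(members))))
      members <- unique(members)
    }
    tibble::tibble(set_id = f[[1]], label = f[[2]], gene = members)
  })
  if (nrow(sets) == 0) {
    sets <- tibble::tibble(set_id = character(), label = character(),
                           gene = character())
  }
  sets
}

# Accepts a gene-set tibble (optionally filtered to one set_id) or a bare
# character vector, and returns the member symbols.
set_members <- function(x, set_id = NULL) {
  if (is.character(x)) return(unique(canonicalize_symbol(x)))
  stopifnot(is.data.frame(x), "gene" %in% names(x))
  if (!is.null(set_id)) x <- x[x$set_id == set_id, , drop = FALSE]
  unique(x$gene)
}

#' Intersection of two gene sets
#'
#' @param a,b Gene sets: tibbles as returned by [load_gene_sets()] (each
#'   restricted to a single set) or character vectors of symbols.
#' @return Sorted character vector of shared symbols.
#' @examples
#' set_overlap(c("CCR2", "THBS1"), c("CCR2", "TNF"))
#' @export
set_overlap <- function(a, b) {
  sort(intersect(set_members(a), set_members(b)))
}

#' Classify genes by gene-set membership
#'
#' Maps every queried gene to the (possibly empty) list of sets containing
#' it, preserving the order in which sets first appear in `sets`.
#'
#' @param genes Character vector of gene symbols.
#' @param sets Gene-set tibble from [load_gene_sets()].
#' @return A tibble with columns `gene` and `set_ids` (list column of
#'   character vectors), one row per input gene.
#' @export
classify_genes <- function(genes, sets) {
  genes <- unique(canonicalize_symbol(as.character(genes)))
  set_order <- unique(sets$set_id)
  tibble::tibble(
    gene = genes,
    set_ids = purrr::map(genes, function(g) {
      set_order[vapply(set_order, function(s) g %in% sets$gene[sets$set_id == s],
                       logical(1))]
    })
  )
}
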