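# Recorded MD5 digests of the packaged reference files; load_pad_fixtures()
# refuses to run on a corrupted installation.
PAD_FIXTURE_MD5 <- c(
  "drugbank_pad.tsv" = "1b245206127053a0c53b4fd1776177e8",
  "mechanism_anti_inflammatory.tsv" = "5f978ecb7bd98e6ad828907727ab6edc",
  "mechanism_pro_angiogenic.tsv" = "00571900cfb247ef43996912819fdeec",
  "network_angiome_synthetic.tsv" = "c5be66c4a28e301469ee1d4ac12d448f",
  "pharmgkb_pad.tsv" = "e8aa15b85493964006ae566cfb6bcb62",
  "strategy_gene_sets.gmt" = "c90e147321f1997bfa32b8195f8d450d"
)

#' Path to a packaged reference file
#'
#' @param file File name under the package's `extdata/`, or nothing to
#'   list the available files.
#' @return Absolute path(s).
#' @export
pad_fixture_path <- function(file = NULL) {
  if (is.null(file)) {
    return(list.files(system.file("extdata", package = "padrepo"),
                      full.names = TRUE))
  }
  path <- system.file("extdata", file, package = "padrepo")
  if (!nzchar(path)) abort(sprintf("no packaged file %s", sQuote(file)))
  path
}

#' Load the packaged PAD repositioning reference data
#'
#' Returns the curated reference inputs shipped with the package: the two
#' strategy gene sets (GO:0016525, 39 anti-angiogenic genes; GO:0050729,
#' 89 pro-inflammatory genes), the approved drug-target relation store in
#' the two source dialects (published candidate-table cells plus labelled
#' synthetic decoy rows), the mechanism-of-action annotation tables that
#' carry each target's published per-network degree, and a small synthetic
#' angiome-like network (SERPINE1 hub). File digests are verified against
#' recorded checksums before parsing.
#'
#' @return A list with elements `gene_sets` (tibble), `store`
#'   (`pad_relations`), `network` ([pad_network()]), and `mechanisms`
#'   (list of two tibbles: `pro_angiogenic` with `degree_angiome`,
#'   `anti_inflammatory` with `degree_immunome`).
#' @examples
#' fx <- load_pad_fixtures()
#' table(fx$gene_sets$set_id)
#' @export
load_pad_fixtures <- function() {
  paths <- vapply(names(PAD_FIXTURE_MD5), pad_fixture_path, "")
  sums <- tools::md5sum(paths)
  bad <- sums != PAD_FIXTURE_MD5
  if (any(bad)) {
    abort(sprintf("packaged file checksum mismatch: %s",
                  paste(names(PAD_FIXTURE_MD5)[bad], collapse = ", ")))
  }
  read_mech <- function(p) {
    tibble::as_tibble(read.delim(p, sep = "\t", comment.char = "#",
                                 check.names = FALSE))
  }
  list(
    gene_sets = load_gene_sets(paths[["strategy_gene_sets.gmt"]]),
    store = merge_relation_stores(
      parse_drugbank_relations(paths[["drugbank_pad.tsv"]]),
      parse_pharmgkb_relations(paths[["pharmgkb_pad.tsv"]])),
    network = read_network(paths[["network_angiome_synthetic.tsv"]],
                           name = "angiome"),
    mechanisms = list(
      pro_angiogenic = read_mech(paths[["mechanism_pro_angiogenic.tsv"]]),
      anti_inflammatory = read_mech(
        paths[["mechanism_anti_inflammatory.tsv"]]))
  )
}
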