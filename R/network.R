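#' Construct a protein-protein interaction network
#'
#' A `pad_network` is a simple undirected graph of gene symbols: no
#' self-loops, no duplicate edges, every edge endpoint present in the node
#' set. Symbols are canonicalized to uppercase on ingest. Edges are stored
#' in canonical order (lexicographically smaller symbol first) so that
#' identical networks serialize identically.
#'
#' @param edges A data frame with character columns `from` and `to`, one row
#'   per interaction, or `NULL` for an edgeless network.
#' @param nodes Optional character vector of additional (possibly isolated)
#'   nodes beyond the edge endpoints.
#' @param name Network label; conventionally one of `"angiome"`,
#'   `"immunome"`, `"arteriome"` or a custom label.
#' @return A `pad_network` object: a list with elements `name` (label),
#'   `nodes` (sorted character vector) and `edges` (tibble with columns
#'   `from`, `to`).
#' @examples
#' pad_network(data.frame(from = "SERPINE1", to = "PLAT"), name = "demo")
#' @export
pad_network <- function(edges = NULL, nodes = character(), name = "custom") {
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- tibble::tibble(from = character(), to = character())
  }
  from <- canonicalize_symbol(as.character(edges$from))
  to <- canonicalize_symbol(as.character(edges$to))
  loops <- from == to
  if (any(loops)) {
    warn(sprintf("dropping %d self-loop edge(s): %s", sum(loops),
                 paste(unique(from[loops]), collapse = ", ")))
    from <- from[!loops]
    to <- to[!loops]
  }
  a <- pmin(from, to)
  b <- pmax(from, to)
  edges <- dplyr::distinct(tibble::tibble(from = a, to = b))
  edges <- dplyr::arrange(edges, .data$from, .data$to)
  nodes <- if (length(nodes)) canonicalize_symbol(nodes) else character()
  nodes <- sort(unique(c(nodes, edges$from, edges$to)))
  structure(list(name = name, nodes = nodes, edges = edges),
            class = "pad_network")
}

#' @export
print.pad_network <- function(x, ...) {
  cat(sprintf("<pad_network '%s'> %d nodes, %d edges\n",
              x$name, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Parse an interaction network from edge-list or SIF text
#'
#' Accepts the two plain-text conventions used for PPI exchange: 2-column
#' whitespace/tab-separated edge lists and 3-column Cytoscape SIF
#' (`nodeA<TAB>interaction<TAB>nodeB`). The two forms may be mixed
#' line-by-line. Lines starting with `#` and blank lines are skipped; a
#' single-token line declares an isolated node. Duplicate edges (including
#' reversed duplicates) collapse to one; self-loops are dropped with a
#' warning.
#'
#' @param lines Character vector of input lines.
#' @param name Network label.
#' @return A [pad_network()].
#' @examples
#' parse_network(c("A\tB", "B\tC"), name = "toy")
#' @export
parse_network <- function(lines, name = "custom") {
  lines <- as.character(lines)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  toks <- strsplit(trimws(lines[keep]), "\\s+")
  n_tok <- lengths(toks)
  if (any(n_tok > 3)) {
    abort(sprintf("malformed network line %d: expected 1-3 fields, got %d",
                  idx[which(n_tok > 3)[1]], max(n_tok)))
  }
  iso <- unlist(lapply(toks[n_tok == 1], `[[`, 1))
  pair2 <- toks[n_tok == 2]
  pair3 <- toks[n_tok == 3]  # SIF order: nodeA interaction nodeB
  from <- c(vapply(pair2, `[[`, "", 1), vapply(pair3, `[[`, "", 1))
  to <- c(vapply(pair2, `[[`, "", 2), vapply(pair3, `[[`, "", 3))
  pad_network(tibble::tibble(from = from, to = to),
              nodes = if (length(iso)) iso else character(),
              name = name)
}

#' Read a network from a file
#'
#' @param path Path to a 2-column edge list or 3-column SIF file.
#' @inheritParams parse_network
#' @return A [pad_network()].
#' @export
read_network <- function(path, name = "custom") {
  parse_network(readLines(path, warn = FALSE), name = name)
}

#' Serialize a network as a canonical sorted edge list
#'
#' Writes one tab-separated edge per line with the lexicographically smaller
#' symbol first, edges sorted, and isolated nodes as trailing single-token
#' lines, so that `parse_network(write_network(net))` reproduces `net`
#' exactly.
#'
#' @param network A [pad_network()].
#' @param path Optional file path; if `NULL` the lines are returned.
#' @return The serialized lines, invisibly when `path` is given.
#' @export
write_network <- function(network, path = NULL) {
  stopifnot(inherits(network, "pad_network"))
  isolated <- setdiff(network$nodes,
                      c(network$edges$from, network$edges$to))
  out <- c(paste(network$edges$from, network$edges$to, sep = "\t"),
           isolated)
  if (is.null(path)) return(out)
  writeLines(out, path)
  invisible(out)
}

as_igraph <- function(network) {
  igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                vertices = network$nodes)
}

#' Node degree with explicit absent flag
#'
#' Degree is the number of distinct interaction partners of a gene in the
#' network. Strategy gene sets legitimately contain genes outside a given
#' network, so querying an absent gene is not an error: it reports degree 0
#' with `in_network = FALSE`.
#'
#' @param network A [pad_network()].
#' @param genes Character vector of gene symbols to query; `NULL` (default)
#'   queries every node of the network.
#' @return A tibble with columns `gene`, `degree` (non-negative integer)
#'   and `in_network` (logical absent flag).
#' @examples
#' net <- parse_network(c("A B", "B C"))
#' network_degree(net, c("B", "Z"))
#' @export
network_degree <- function(network, genes = NULL) {
  stopifnot(inherits(network, "pad_network"))
  if (is.null(genes)) {
    genes <- network$nodes
  } else {
    genes <- canonicalize_symbol(as.character(genes))
  }
  deg <- if (length(network$nodes)) {
    igraph::degree(as_igraph(network), loops = FALSE)
  } else {
    setNames(integer(), character())
  }
  present <- genes %in% network$nodes
  tibble::tibble(
    gene = genes,
    degree = as.integer(ifelse(present, deg[genes], 0L)),
    in_network = present
  )
}

#' Degree table of a network
#'
#' One row per node, sorted by decreasing degree then symbol. The degrees
#' satisfy the handshake lemma: their sum is exactly twice the edge count.
#'
#' @param network A [pad_network()].
#' @return A tibble with columns `gene`, `degree`, `in_network` (all `TRUE`)
#'   and the network name as attribute `network_name`.
#' @export
degree_table <- function(network) {
  out <- dplyr::arrange(network_degree(network),
                        dplyr::desc(.data$degree), .data$gene)
  attr(out, "network_name") <- network$name
  out
}

#' @method tidy pad_network
#' @export
tidy.pad_network <- function(x, ...) x$edges

#' @method glance pad_network
#' @export
glance.pad_network <- function(x, ...) {
  tibble::tibble(name = x$name, n_nodes = length(x$nodes),
                 n_edges = nrow(x$edges))
}
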