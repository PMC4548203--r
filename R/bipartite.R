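#' Build a bipartite drug-target graph from a candidate table
#'
#' One target node per candidate gene, one drug node per distinct drug
#' name, one edge per (drug, gene) pairing. Edges only ever connect a drug
#' to a target (strict two-coloring); node display hints follow the
#' published figures (targets: pink circles; drugs: blue squares). Drug
#' node identity is the normalized lowercase name.
#'
#' @param candidates A `pad_candidates` table from [candidate_table()], or
#'   any tibble with a `gene` column and a `drugs` list column (a `degree`
#'   column is carried onto target nodes when present).
#' @return A `pad_bipartite` object: list with `nodes` (tibble: `node`,
#'   `role`, `shape`, `color`, `degree`) and `edges` (tibble: `drug`,
#'   `gene`).
#' @export
build_bipartite <- function(candidates) {
  stopifnot(is.data.frame(candidates),
            all(c("gene", "drugs") %in% names(candidates)))
  edges <- tidyr::unnest(
    tibble::tibble(gene = candidates$gene,
                   drug = purrr::map(candidates$drugs,
                                     function(d) sort(unique(
                                       normalize_drug_name(d))))),
    "drug")
  edges <- dplyr::distinct(edges[, c("drug", "gene")])
  deg <- if ("degree" %in% names(candidates)) {
    setNames(candidates$degree, candidates$gene)
  } else {
    setNames(rep(NA_integer_, nrow(candidates)), candidates$gene)
  }
  targets <- unique(edges$gene)
  drugs <- unique(edges$drug)
  nodes <- tibble::tibble(
    node = c(targets, drugs),
    role = rep(c("target", "drug"), c(length(targets), length(drugs))),
    shape = rep(c("circle", "square"), c(length(targets), length(drugs))),
    color = rep(c("pink", "blue"), c(length(targets), length(drugs))),
    degree = c(as.integer(deg[targets]), rep(NA_integer_, length(drugs)))
  )
  structure(list(nodes = nodes, edges = edges), class = "pad_bipartite")
}

#' @export
print.pad_bipartite <- function(x, ...) {
  cat(sprintf("<pad_bipartite> %d targets, %d drugs, %d edges\n",
              sum(x$nodes$role == "target"), sum(x$nodes$role == "drug"),
              nrow(x$edges)))
  invisible(x)
}

#' @method tidy pad_bipartite
#' @export
tidy.pad_bipartite <- function(x, ...) x$edges

#' @method glance pad_bipartite
#' @export
glance.pad_bipartite <- function(x, ...) {
  tibble::tibble(n_targets = sum(x$nodes$role == "target"),
                 n_drugs = sum(x$nodes$role == "drug"),
                 n_edges = nrow(x$edges))
}

#' Serialize a bipartite graph as Cytoscape SIF
#'
#' One line per edge: `drug<TAB>targets<TAB>GENE`. Re-parsing with
#' [read_sif()] reproduces the edge set exactly.
#'
#' @param graph A `pad_bipartite` graph.
#' @param path Output path, or `NULL` to return the lines.
#' @return SIF lines, invisibly when `path` is given.
#' @export
write_sif <- function(graph, path = NULL) {
  stopifnot(inherits(graph, "pad_bipartite"))
  lines <- paste(graph$edges$drug, "targets", graph$edges$gene, sep = "\t")
  if (is.null(path)) return(lines)
  if (!dir.exists(dirname(path))) {
    abort(sprintf("cannot write SIF: directory %s does not exist",
                  sQuote(dirname(path))))
  }
  writeLines(lines, path)
  invisible(lines)
}

#' Read drug-target edges from SIF text
#'
#' @param lines SIF lines (`source<TAB>relation<TAB>target`) or a file path.
#' @return A tibble with columns `drug`, `gene`.
#' @export
read_sif <- function(lines) {
  if (length(lines) == 1 && file.exists(lines)) {
    lines <- readLines(lines, warn = FALSE)
  }
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) != 3
  if (any(bad)) {
    abort(sprintf("malformed SIF line %d: expected 3 tab-separated fields",
                  which(bad)[1]))
  }
  dplyr::distinct(tibble::tibble(
    drug = vapply(parts, `[[`, "", 1),
    gene = vapply(parts, `[[`, "", 3)))
}

#' Serialize a bipartite graph as GraphML
#'
#' GraphML 1.0 with node attributes `role` (target/drug), `shape`, `color`
#' and target `degree`, consumable by Cytoscape and igraph. The encoded
#' edge set is identical to the SIF serialization.
#'
#' @param graph A `pad_bipartite` graph.
#' @param path Output path, or `NULL` to return the XML as a string.
#' @return The GraphML document as a string, invisibly when `path` is
#'   given.
#' @export
write_graphml <- function(graph, path = NULL) {
  stopifnot(inherits(graph, "pad_bipartite"))
  doc <- xml2::xml_new_root(
    "graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns")
  keys <- list(role = "string", shape = "string", color = "string",
               degree = "int")
  for (k in names(keys)) {
    xml2::xml_add_child(doc, "key", id = k, `for` = "node",
                        attr.name = k, attr.type = keys[[k]])
  }
  g <- xml2::xml_add_child(doc, "graph", id = "drug_target",
                           edgedefault = "undirected")
  for (i in seq_len(nrow(graph$nodes))) {
    nd <- xml2::xml_add_child(g, "node", id = graph$nodes$node[i])
    xml2::xml_add_child(nd, "data", key = "role", graph$nodes$role[i])
    xml2::xml_add_child(nd, "data", key = "shape", graph$nodes$shape[i])
    xml2::xml_add_child(nd, "data", key = "color", graph$nodes$color[i])
    if (!is.na(graph$nodes$degree[i])) {
      xml2::xml_add_child(nd, "data", key = "degree",
                          as.character(graph$nodes$degree[i]))
    }
  }
  for (i in seq_len(nrow(graph$edges))) {
    xml2::xml_add_child(g, "edge",
                        source = graph$edges$drug[i],
                        target = graph$edges$gene[i])
  }
  out <- as.character(doc)
  if (is.null(path)) return(out)
  xml2::write_xml(doc, path)
  invisible(out)
}

#' Node-attribute table of a bipartite graph
#'
#' @param graph A `pad_bipartite` graph.
#' @param path Output path for a TSV (`node`, `role`, `shape`, `color`,
#'   `degree`), or `NULL` to return the lines.
#' @return TSV lines, invisibly when `path` is given.
#' @export
write_node_attributes <- function(graph, path = NULL) {
  stopifnot(inherits(graph, "pad_bipartite"))
  n <- graph$nodes
  lines <- c("node\trole\tshape\tcolor\tdegree",
             paste(n$node, n$role, n$shape, n$color,
                   ifelse(is.na(n$degree), "", n$degree), sep = "\t"))
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' PubMed-style literature evidence queries
#'
#' Instantiates the exact keyword templates used to collect literature
#' evidence: for a gene, `"(GENE) AND (PAD OR coronary arterial disease)"`;
#' for a drug, `"(drug) AND angiogenesis"` or `"(drug) AND inflammation"`
#' depending on the strategy under scrutiny. Strings are generated only,
#' never sent anywhere.
#'
#' @param gene Gene symbol(s).
#' @return Character vector of query strings.
#' @examples
#' evidence_query("SERPINE1")
#' evidence_query_drug("carvedilol", "angiogenesis")
#' @export
evidence_query <- function(gene) {
  gene <- canonicalize_symbol(as.character(gene))
  sprintf("(%s) AND (PAD OR coronary arterial disease)", gene)
}

#' @param drug Drug name(s); used verbatim.
#' @param topic `"angiogenesis"` or `"inflammation"`.
#' @rdname evidence_query
#' @export
evidence_query_drug <- function(drug, topic = c("angiogenesis",
                                                "inflammation")) {
  topic <- match.arg(topic)
  drug <- trimws(as.character(drug))
  if (any(!nzchar(drug))) abort("drug name must be non-empty")
  sprintf("(%s) AND %s", drug, topic)
}
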