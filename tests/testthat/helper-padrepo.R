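# Shared fixture builders and independent brute-force oracles. The oracles
# deliberately avoid the package's own code paths (plain loops over plain
# vectors) so that tests compare two independent routes.

fixtures <- load_pad_fixtures()

# degree by direct incidence count over the edge list
oracle_degree <- function(network, gene) {
  sum(network$edges$from == gene) + sum(network$edges$to == gene)
}

# two-loop candidate-gene oracle: set member x relation scan under the
# approved/target/source predicate
oracle_candidates <- function(members, store, sources = "drugbank",
                              kinds = "target", approved_only = TRUE) {
  hits <- character()
  drug_ok <- function(id, src) {
    g <- store$drugs$groups[store$drugs$drug_id == id &
                              store$drugs$source == src][[1]]
    !approved_only || "approved" %in% g
  }
  for (g in members) {
    for (i in seq_len(nrow(store$relations))) {
      r <- store$relations[i, ]
      if (r$gene == g && r$relation_kind %in% kinds &&
          r$source %in% sources && drug_ok(r$drug_id, r$source)) {
        hits <- c(hits, g)
        break
      }
    }
  }
  sort(unique(hits))
}

# minimal drugbank-dialect store built in code
toy_db_lines <- function(rows) {
  c(paste("relation_type", "drug_id", "drug_name", "groups", "partner",
          sep = "\t"), rows)
}
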