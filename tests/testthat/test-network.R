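test_that("edge-list parsing builds a simple undirected network", {
  net <- parse_network(c("A B", "B C"))
  expect_equal(length(net$nodes), 3)
  expect_equal(nrow(net$edges), 2)

  # reversed duplicates collapse, self-loops drop with a warning
  expect_warning(net2 <- parse_network(c("A B", "B A", "A A")),
                 "self-loop")
  expect_equal(sort(net2$nodes), c("A", "B"))
  expect_equal(nrow(net2$edges), 1)
})

test_that("SIF lines, comments, isolated nodes and case folding parse", {
  net <- parse_network(c("# a comment", "", "a\tpp\tb", "b\tpp\tc",
                         "lonely"))
  expect_setequal(net$nodes, c("A", "B", "C", "LONELY"))
  expect_equal(nrow(net$edges), 2)
  expect_equal(network_degree(net, "LONELY")$degree, 0L)
  expect_true(network_degree(net, "LONELY")$in_network)
})

test_that("malformed and empty input are handled per contract", {
  expect_error(parse_network("A B C D"), "malformed network line 1")
  empty <- parse_network(character())
  expect_equal(length(empty$nodes), 0)
  expect_equal(nrow(empty$edges), 0)
  expect_equal(nrow(degree_table(empty)), 0)
})

test_that("degree matches neighbor count, with absent flag for missing genes", {
  path <- parse_network(c("A B", "B C"))
  expect_equal(network_degree(path, "B")$degree, 2L)
  z <- network_degree(path, "Z")
  expect_equal(z$degree, 0L)
  expect_false(z$in_network)

  # star with hub H and 14 leaves, the published angiome degree of SERPINE1
  star <- parse_network(paste("H", sprintf("L%02d", 1:14)))
  expect_equal(network_degree(star, "H")$degree, 14L)

  # fixture network reproduces that hub degree
  expect_equal(network_degree(fixtures$network, "SERPINE1")$degree, 14L)
})

test_that("degree tables satisfy the handshake lemma", {
  tri <- parse_network(c("A B", "B C", "A C"))
  dt <- degree_table(tri)
  expect_true(all(dt$degree == 2))
  expect_equal(sum(dt$degree), 2L * nrow(tri$edges))

  set.seed(11)
  for (i in 1:5) {
    n <- sample(5:40, 1)
    m <- sample(0:(n * (n - 1) / 2), 1)
    g <- igraph::sample_gnm(n, m)
    el <- igraph::as_edgelist(g)
    net <- pad_network(tibble::tibble(from = sprintf("N%02d", el[, 1]),
                                      to = sprintf("N%02d", el[, 2])),
                       nodes = sprintf("N%02d", 1:n))
    dt <- degree_table(net)
    expect_equal(sum(dt$degree), 2L * nrow(net$edges))
    expect_true(all(dt$degree <= length(net$nodes) - 1))
    # independent per-node oracle: direct incidence count
    for (gene in sample(net$nodes, min(5, length(net$nodes)))) {
      expect_equal(dt$degree[dt$gene == gene], oracle_degree(net, gene))
    }
  }
})

test_that("serialization round-trips and parsing is idempotent", {
  sc <- generate_synthetic(synthetic_spec(seed = 7, n_genes = 50,
                                          n_edges = 120))
  net <- sc$network
  lines <- write_network(net)
  back <- parse_network(lines, name = net$name)
  expect_identical(back$nodes, net$nodes)
  expect_identical(back$edges, net$edges)
  # idempotence: parse(serialize(parse(x))) == parse(x)
  expect_identical(parse_network(write_network(back)),
                   parse_network(lines))
})

test_that("network tidiers report edges and summary", {
  net <- parse_network(c("A B", "B C"), name = "toy")
  expect_equal(nrow(tidy(net)), 2)
  g <- glance(net)
  expect_equal(g$name, "toy")
  expect_equal(g$n_nodes, 3L)
})
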