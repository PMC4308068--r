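edge_tbl <- function(...) {
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  tibble::tibble(gene_a = m[, 1], gene_b = m[, 2])
}

test_that("graphs build deduplicated from records or stability classes", {
  tri <- build_epistasis_graph(edge_tbl("a", "b", "b", "c", "a", "c"))
  expect_equal(igraph::gorder(tri), 3L)
  expect_equal(igraph::gsize(tri), 3L)
  # duplicate records collapse to a single edge
  dup <- build_epistasis_graph(edge_tbl("a", "b", "b", "a", "a", "b"))
  expect_equal(igraph::gsize(dup), 1L)
  # empty edge set is a valid empty graph
  empty <- build_epistasis_graph(edge_tbl("a", "b")[0, ])
  expect_equal(igraph::gorder(empty), 0L)
  # stability-class filtering: the two-carbon stable class is one edge
  tc <- twocarbon_records()
  st <- epistasis_stability(tc$records[c("glucose_low", "alt_carbon")])
  g <- build_epistasis_graph(st, "stable")
  ed <- igraph::as_data_frame(g)
  expect_equal(nrow(ed), 1L)
  expect_setequal(unlist(ed[1, c("from", "to")]), c("g1", "g2"))
})

test_that("degree distributions tabulate exactly", {
  tri <- build_epistasis_graph(edge_tbl("a", "b", "b", "c", "a", "c"))
  dd <- degree_distribution_table(tri)
  expect_equal(dd$degree, 2L)
  expect_equal(dd$frequency, 3L)
  star <- build_epistasis_graph(
    edge_tbl("hub", "l1", "hub", "l2", "hub", "l3", "hub", "l4", "hub", "l5"))
  ds <- degree_distribution_table(star)
  expect_equal(ds$frequency[ds$degree == 1], 5L)
  expect_equal(ds$frequency[ds$degree == 5], 1L)
  expect_error(degree_distribution_table(igraph::make_empty_graph(0)),
               "empty graph")
  # heavy-tailed preferential-attachment graph is reproducible by seed
  set.seed(42)
  g1 <- igraph::sample_pa(60, m = 2, directed = FALSE)
  set.seed(42)
  g2 <- igraph::sample_pa(60, m = 2, directed = FALSE)
  expect_identical(degree_distribution_table(g1),
                   degree_distribution_table(g2))
  expect_gt(max(degree_distribution_table(g1)$degree), 10)
})

test_that("network statistics match hand-enumerated values", {
  tri <- build_epistasis_graph(edge_tbl("a", "b", "b", "c", "a", "c"))
  st <- network_stats(tri)
  expect_equal(st$avg_path_length, 1)
  expect_equal(st$avg_clustering, 1)
  expect_equal(st$avg_closeness, 1)
  # path graph a-b-c: pairs at distances 1, 1, 2
  pth <- build_epistasis_graph(edge_tbl("a", "b", "b", "c"))
  sp <- network_stats(pth)
  expect_equal(sp$avg_path_length, 4 / 3)
  expect_equal(sp$avg_clustering, 0)
  # two disjoint edges: connected pairs only; closeness within components
  two <- build_epistasis_graph(edge_tbl("a", "b", "c", "d"))
  s2 <- network_stats(two)
  expect_equal(s2$avg_path_length, 1)
  expect_equal(s2$avg_closeness, 1)
})

test_that("network statistics match the all-pairs BFS oracle", {
  for (seed in 1:3) {
    set.seed(seed)
    g <- igraph::sample_gnp(40, 0.08)
    st <- network_stats(g)
    or <- oracle_network_stats(g)
    expect_equal(st$avg_path_length, or$avg_path_length, tolerance = 1e-12)
    expect_equal(st$avg_clustering, or$avg_clustering, tolerance = 1e-12)
    expect_equal(st$avg_closeness, or$avg_closeness, tolerance = 1e-12)
  }
})

test_that("adding an edge to a connected graph never lengthens average paths", {
  # (on a disconnected graph a bridging edge adds new, long connected pairs,
  # so the connected-pair average can legitimately rise)
  g <- igraph::make_tree(25, children = 2, mode = "undirected")
  base <- network_stats(g)$avg_path_length
  # add edges between the first non-adjacent pair found, repeatedly
  for (k in 1:5) {
    A <- as.matrix(igraph::as_adjacency_matrix(g))
    diag(A) <- 1
    gap <- which(A == 0, arr.ind = TRUE)
    if (nrow(gap) == 0) break
    g <- igraph::add_edges(g, as.integer(gap[1, ]))
    nxt <- network_stats(g)$avg_path_length
    expect_lte(nxt, base + 1e-12)
    base <- nxt
  }
})

test_that("a dense stable core beats a dynamic periphery on all three stats", {
  set.seed(5)
  stable <- igraph::sample_gnp(25, 0.35)
  comp <- igraph::components(stable)
  stable <- igraph::induced_subgraph(
    stable, which(comp$membership == which.max(comp$csize)))
  dynamic <- igraph::make_tree(40, children = 2, mode = "undirected")
  ss <- network_stats(stable)
  sd <- network_stats(dynamic)
  expect_lt(ss$avg_path_length, sd$avg_path_length)
  expect_gt(ss$avg_clustering, sd$avg_clustering)
  expect_gt(ss$avg_closeness, sd$avg_closeness)
})

test_that("harmonic closeness variant is available and bounded", {
  two <- build_epistasis_graph(edge_tbl("a", "b", "c", "d"))
  h <- network_stats(two, closeness = "harmonic")
  # each node reaches 1 of 3 others at distance 1
  expect_equal(h$avg_closeness, 1 / 3, tolerance = 1e-12)
})
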