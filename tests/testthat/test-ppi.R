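# PPI graph construction, topology metrics, summary statistics, exports.

test_that("build_graph collapses duplicates, drops self-loops, thresholds", {
  edges <- data.frame(node1 = c("A", "B", "C"), node2 = c("B", "A", "C"),
                      combined_score = c(0.9, 0.5, 0.8))
  g <- build_graph(edges, score_threshold = 0.4)
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$combined_score, 0.9)  # duplicate keeps max score
  expect_equal(sort(g$nodes), c("A", "B"))
  expect_error(build_graph(data.frame(node1 = "A", node2 = "B",
                                      combined_score = 1.2)),
               "outside \\[0, 1\\]")
})

test_that("threshold 1 empties the edge set but keeps the universe", {
  edges <- data.frame(node1 = "A", node2 = "B", combined_score = 0.9)
  g <- build_graph(edges, score_threshold = 1,
                   node_universe = c("A", "B", "C"))
  expect_equal(nrow(g$edges), 0L)
  expect_equal(sort(g$nodes), c("A", "B", "C"))
  g2 <- build_graph(edges, score_threshold = 1, node_universe = c("A", "B"),
                    drop_isolated = TRUE)
  expect_equal(length(g2$nodes), 0L)
})

test_that("universe-stray endpoints warn and are retained", {
  edges <- data.frame(node1 = "A", node2 = "Z", combined_score = 0.9)
  expect_warning(g <- build_graph(edges, node_universe = c("A", "B")),
                 "absent from the universe")
  expect_true(all(c("A", "B", "Z") %in% g$nodes))
})

test_that("raising the score threshold never adds edges", {
  set.seed(5)
  edges <- random_edges(10, p = 0.5)
  edges$combined_score <- runif(nrow(edges), 0, 1)
  prev <- Inf
  for (th in c(0, 0.25, 0.5, 0.75, 1)) {
    g <- build_graph(edges, score_threshold = th)
    expect_lte(nrow(g$edges), prev)
    prev <- nrow(g$edges)
  }
})

test_that("topology matches hand-derived values on canonical graphs", {
  star <- build_graph(star_graph("HUB", sprintf("L%d", 1:4)))
  ts <- topology(star)
  hub <- ts[ts$gene == "HUB", ]
  expect_equal(hub$degree, 4L)
  expect_equal(hub$betweenness, 6)        # C(4,2) leaf pairs
  expect_equal(hub$coreness, 1L)
  expect_equal(hub$closeness, 1)
  leaf <- ts[ts$gene == "L1", ]
  expect_equal(leaf$betweenness, 0)

  tri <- build_graph(complete_graph(c("A", "B", "C")))
  tt <- topology(tri)
  expect_equal(tt$degree, rep(2L, 3))
  expect_equal(tt$coreness, rep(2L, 3))
  expect_equal(tt$closeness, rep(1, 3))

  k4 <- build_graph(complete_graph(c("A", "B", "C", "D")))
  expect_equal(topology(k4)$coreness, rep(3L, 4))
})

test_that("topology metrics agree with brute-force oracles on random graphs", {
  set.seed(99)
  for (rep in 1:30) {
    n <- sample(4:12, 1)
    edges <- random_edges(n, p = runif(1, 0.15, 0.6))
    nodes <- sprintf("N%02d", seq_len(n))
    g <- build_graph(edges, score_threshold = 0, node_universe = nodes)
    tp <- topology(g)
    rownames(tp) <- tp$gene
    expect_equal(tp[nodes, "betweenness"],
                 unname(bf_betweenness(nodes, g$edges)), tolerance = 1e-10)
    expect_equal(tp[nodes, "closeness"],
                 unname(bf_closeness(nodes, g$edges)), tolerance = 1e-10)
    expect_equal(tp[nodes, "coreness"],
                 unname(bf_coreness(nodes, g$edges)))
    # node-wise invariants
    expect_true(all(tp$coreness <= tp$degree))
    expect_true(all(tp$closeness >= 0 & tp$closeness <= 1))
    # handshake
    expect_equal(sum(tp$degree), 2L * nrow(g$edges))
  }
})

test_that("network_summary matches pair enumeration", {
  pth <- build_graph(path_graph(c("A", "B", "C")))
  s <- network_summary(pth)
  expect_equal(s$avg_degree, 4 / 3)
  expect_equal(s$avg_shortest_path, 4 / 3)   # pairs {1, 1, 2}
  expect_equal(s$avg_clustering, 0)
  expect_equal(s$n_excluded_pairs, 0L)

  tri <- network_summary(build_graph(complete_graph(c("A", "B", "C"))))
  expect_equal(tri$avg_degree, 2)
  expect_equal(tri$avg_shortest_path, 1)
  expect_equal(tri$avg_clustering, 1)

  two <- network_summary(build_graph(data.frame(
    node1 = c("A", "C"), node2 = c("B", "D"), combined_score = 1)))
  expect_equal(two$avg_shortest_path, 1)     # only the 2 connected pairs
  expect_equal(two$n_excluded_pairs, 4L)

  expect_error(network_summary(build_graph(
    data.frame(node1 = character(0), node2 = character(0),
               combined_score = numeric(0)))), "no nodes")
})

test_that("rank_hubs is deterministic under the stated tie-breaks", {
  rows <- data.frame(gene = c("B", "A", "C", "D"),
                     degree = c(3L, 3L, 5L, 3L),
                     betweenness = c(2, 7, 0, 2))
  r <- rank_hubs(rows)
  expect_equal(r$gene, c("C", "A", "B", "D"))
})

test_that("TSV export round-trips nodes, edges and scores", {
  set.seed(21)
  nodes <- sprintf("N%02d", 1:50)
  edges <- random_edges(50, p = 0.05)
  g <- build_graph(edges, score_threshold = 0, node_universe = nodes)
  f <- withr::local_tempfile(fileext = ".tsv")
  export_graph(g, f, "tsv")
  g2 <- read_ppi_tsv(f)
  expect_setequal(g2$nodes, g$nodes)
  expect_equal(g2$edges[order(g2$edges$node1, g2$edges$node2), ],
               g$edges[order(g$edges$node1, g$edges$node2), ],
               ignore_attr = TRUE)
})

test_that("SIF export writes pp triples and bare isolated nodes", {
  g <- build_graph(data.frame(node1 = "A", node2 = "B", combined_score = 1),
                   node_universe = c("A", "B", "C"))
  f <- withr::local_tempfile(fileext = ".sif")
  export_graph(g, f, "sif")
  expect_equal(readLines(f), c("A\tpp\tB", "C"))
  expect_error(export_graph(g, f, "dot"), "arg")
})

test_that("empty graph with isolated universe exports node-only TSV", {
  g <- build_graph(data.frame(node1 = character(0), node2 = character(0),
                              combined_score = numeric(0)),
                   node_universe = c("A", "B", "C"))
  f <- withr::local_tempfile(fileext = ".tsv")
  export_graph(g, f, "tsv")
  g2 <- read_ppi_tsv(f)
  expect_setequal(g2$nodes, c("A", "B", "C"))
  expect_equal(nrow(g2$edges), 0L)
})

test_that("graphml export is readable by igraph", {
  g <- build_graph(data.frame(node1 = c("A", "B"), node2 = c("B", "C"),
                              combined_score = c(0.5, 0.9)))
  f <- withr::local_tempfile(fileext = ".graphml")
  export_graph(g, f, "graphml")
  ig <- igraph::read_graph(f, format = "graphml")
  expect_equal(igraph::gorder(ig), 3)
  expect_equal(igraph::gsize(ig), 2)
})
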