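# Generators: exact planted counts, determinism, recovery by the pipeline.

test_that("gen_ingredients plants exact screen outcomes", {
  sim <- gen_ingredients(per_herb_counts = c(47L, 17L, 10L),
                         pass_counts = c(3L, 2L, 5L), seed = 11L)
  expect_equal(vapply(sim$tables, nrow, integer(1)),
               c(`Radix Scrophulariae` = 47L,
                 `Bulbus Fritillariae ferganensis` = 17L,
                 `Concha Ostreae` = 10L))
  cands <- select_candidates(sim$tables)
  expect_equal(nrow(cands), 9L)   # 3 + 2 + 5 with one cross-herb duplicate
  expect_equal(nrow(cands), sim$truth$n_candidates)
  expect_equal(sum(cands$n_herbs == 2L), 1L)
  expect_setequal(cands$name, unique(unlist(sim$truth$planted_pass_names)))
})

test_that("gen_ingredients degenerate and error cases", {
  none <- gen_ingredients(c(5L, 5L, 5L), c(0L, 0L, 0L),
                          shared_pass_herbs = NULL, seed = 2L)
  expect_equal(nrow(select_candidates(none$tables)), 0L)
  expect_error(gen_ingredients(c(2L, 2L, 2L), c(3L, 0L, 0L)), "infeasible")
  expect_error(gen_ingredients(c(5L, 5L, 5L), c(0L, 1L, 1L),
                               shared_pass_herbs = c(1L, 2L)),
               "infeasible shared")
})

test_that("generators are bit-identical under the same seed", {
  a <- gen_ingredients(seed = 33L)
  b <- gen_ingredients(seed = 33L)
  expect_identical(a, b)
  expect_false(identical(a, gen_ingredients(seed = 34L)))
  cands <- select_candidates(a$tables)
  expect_identical(gen_target_maps(cands, seed = 5L),
                   gen_target_maps(cands, seed = 5L))
})

test_that("gen_target_maps hits exact per-herb and union sizes", {
  sim <- gen_ingredients(seed = 11L)
  cands <- select_candidates(sim$tables)
  tm <- gen_target_maps(cands, per_herb_target_counts = c(58L, 46L, 27L),
                        union_size = 71L, seed = 7L)
  per_herb <- split(tm$map$raw_target, tm$map$herb_latin)
  expect_equal(sort(unname(vapply(per_herb, function(x) length(unique(x)),
                                  integer(1)))), c(27L, 46L, 58L))
  expect_equal(length(unique(tm$map$raw_target)), 71L)
  # the union stage recovers the planted union exactly
  sets <- lapply(split(tm$map$raw_target, tm$map$ingredient), gene_set)
  expect_setequal(union_targets(unname(sets))$genes, tm$truth$union_targets)
  # every candidate ingredient carries at least one target
  expect_setequal(unique(tm$map$ingredient), cands$name)
})

test_that("gen_target_maps disjoint and nested allocations", {
  cands <- data.frame(name = c("i1", "i2"), herbs = c("H1", "H2"),
                      n_herbs = 1L)
  disj <- gen_target_maps(cands, per_herb_target_counts = c(10L, 15L),
                          union_size = 25L, herb_order = c("H1", "H2"),
                          seed = 1L)
  expect_equal(length(unique(disj$map$raw_target)), 25L)
  expect_equal(length(intersect(
    disj$map$raw_target[disj$map$herb_latin == "H1"],
    disj$map$raw_target[disj$map$herb_latin == "H2"])), 0L)
  nest <- gen_target_maps(cands, per_herb_target_counts = c(20L, 5L),
                          union_size = 20L, herb_order = c("H1", "H2"),
                          seed = 1L)
  expect_equal(length(unique(nest$map$raw_target)), 20L)
  expect_error(gen_target_maps(cands, per_herb_target_counts = c(5L, 5L),
                               union_size = 20L,
                               herb_order = c("H1", "H2")), "infeasible")
})

test_that("gen_disease_lists plants exact integration and overlap counts", {
  drug <- gene_set(sprintf("G%03d", 1:71), "drug")
  dis <- gen_disease_lists(drug, 245L, 93L, 17L, 29L, seed = 13L)
  a <- gene_set(dis$source_a, "a")
  b <- gene_set(dis$source_b, "b")
  expect_equal(length(a$genes), 245L)
  expect_equal(length(b$genes), 93L)
  expect_equal(length(intersect(a$genes, b$genes)), 17L)
  integrated <- integrate_disease_targets(a, b)
  expect_equal(length(integrated$genes), 321L)
  v <- venn(drug, integrated)
  expect_equal(v$size_intersection, 29L)
  expect_equal(v$pct_of_b, 9.03)
  # zero source overlap makes the union additive
  dis0 <- gen_disease_lists(drug, 245L, 93L, 0L, 29L, seed = 13L)
  expect_equal(length(union(dis0$source_a, dis0$source_b)), 338L)
  expect_error(gen_disease_lists(drug, 10L, 5L, 8L, 2L), "infeasible")
  expect_error(gen_disease_lists(gene_set("A"), 10L, 5L, 2L, 5L),
               "infeasible drug_overlap")
})

test_that("gen_ppi draws exactly m edges and plants cliques", {
  nodes <- sprintf("P%02d", 1:29)
  sim <- gen_ppi(nodes, "gnm", m = 86L, seed = 4L)
  g0 <- build_graph(sim$edges, score_threshold = 0, node_universe = nodes)
  expect_equal(network_summary(g0)$n_edges, 86L)
  expect_true(all(sim$edges$combined_score >= 0.15 &
                    sim$edges$combined_score <= 0.999))
  # truth lists exactly the nodes connected at the 0.4 cut
  g4 <- build_graph(sim$edges, score_threshold = 0.4, node_universe = nodes)
  expect_setequal(sim$truth$connected_nodes,
                  unique(c(g4$edges$node1, g4$edges$node2)))

  none <- gen_ppi(nodes, "gnm", m = 0L, seed = 4L)
  expect_equal(nrow(none$edges), 0L)

  mod <- gen_ppi(nodes, "planted_module", m = 10L,
                 module_nodes = nodes[1:5], seed = 4L)
  g <- build_graph(mod$edges, score_threshold = 0.4, node_universe = nodes)
  tp <- topology(g)
  expect_true(all(tp$coreness[tp$gene %in% nodes[1:5]] >= 4L))
  expect_error(gen_ppi(nodes[1:3], "gnm", m = 10L), "infeasible")
})

test_that("gen_annotations respects sizes and the null has no plants", {
  universe <- sprintf("G%03d", 1:100)
  query <- sample(universe, 20)
  ann <- gen_annotations(universe, n_terms = 15L,
                         term_size_range = c(5L, 50L), n_planted = 1L,
                         enrichment_factor = 6, query = query, seed = 9L)
  sizes <- vapply(ann$annotations$terms, length, integer(1))
  expect_true(all(sizes >= 5L & sizes <= 50L))
  expect_equal(ann$truth$planted_terms, "planted_01")
  null <- gen_annotations(universe, n_terms = 15L, enrichment_factor = 1,
                          query = query, seed = 9L)
  expect_equal(null$truth$planted_terms, character(0))
  expect_false(any(grepl("planted", names(null$annotations$terms))))
  expect_error(gen_annotations(universe[1:10], term_size_range = c(5L, 50L)),
               "exceed")
})
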