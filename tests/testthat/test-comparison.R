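test_that("hamming distance matches hand-computed values", {
  a <- make_graph(c("x", "y", "z"), "x", "y", 0.5)
  b <- make_graph(c("x", "y", "z"), "x", "z", 0.7)
  expect_equal(hamming_distance(a, a), 0)
  expect_equal(hamming_distance(a, b), 2 / 3)
  comp <- make_graph(c("x", "y", "z"), "x", "z", 1, "y", "z", 1)
  expect_equal(hamming_distance(a, comp), 1)   # complementary edge sets
  expect_error(hamming_distance(a, make_graph(c("x", "y", "w"), "x", "y", 1)),
               "identical node set")
})

test_that("jaccard index matches hand-computed values", {
  a <- make_graph(c("x", "y", "z"), "x", "y", 1, "y", "z", 1)
  b <- make_graph(c("x", "y", "z"), "y", "z", 1, "x", "z", 1)
  expect_equal(jaccard_index(a, a), 1)
  expect_equal(jaccard_index(a, b), 1 / 3)     # {e1,e2} vs {e2,e3}
  disjoint <- make_graph(c("x", "y", "z"), "x", "z", 1)
  only_xy <- make_graph(c("x", "y", "z"), "x", "y", 1)
  expect_equal(jaccard_index(only_xy, disjoint), 0)
  empty <- weighted_graph(c("x", "y", "z"), matrix(0, 3, 3))
  expect_equal(jaccard_index(empty, empty), 1) # 0/0 read as identical
})

test_that("spectral distance compares algebraic connectivities", {
  expect_equal(spectral_distance(unit_triangle(), unit_triangle()), 0)
  expect_equal(spectral_distance(unit_triangle(), unit_path3()), 2)  # |3 - 1|
  frag <- make_graph(c("a", "b", "c", "d"), "a", "b", 1, "c", "d", 1)
  expect_equal(fiedler_value(frag), 0, tolerance = 1e-12)
  conn <- make_graph(c("a", "b", "c", "d"),
                     "a", "b", 1, "b", "c", 1, "c", "d", 1)
  expect_equal(spectral_distance(frag, conn), fiedler_value(conn))
})

test_that("metrics are symmetric and agree at the extremes", {
  for (s in 1:6) {
    ga <- random_connected_graph(8, p = 0.4, seed = 7000 + s)
    gb <- random_connected_graph(8, p = 0.4, seed = 7100 + s)
    gb$nodes <- ga$nodes
    dimnames(gb$weights) <- dimnames(ga$weights)
    expect_equal(hamming_distance(ga, gb), hamming_distance(gb, ga))
    expect_equal(jaccard_index(ga, gb), jaccard_index(gb, ga))
    expect_equal(spectral_distance(ga, gb), spectral_distance(gb, ga))
    expect_equal(hamming_distance(ga, ga), 0)
    expect_equal(jaccard_index(ga, ga), 1)
  }
  # hamming triangle inequality on binarized graphs
  g1 <- random_connected_graph(7, p = 0.3, seed = 1)
  g2 <- random_connected_graph(7, p = 0.5, seed = 2)
  g3 <- random_connected_graph(7, p = 0.7, seed = 3)
  for (g in list(g2, g3)) {
    g$nodes <- g1$nodes
    dimnames(g$weights) <- dimnames(g1$weights)
  }
  g2$nodes <- g3$nodes <- g1$nodes
  dimnames(g2$weights) <- dimnames(g3$weights) <- dimnames(g1$weights)
  expect_lte(hamming_distance(g1, g3),
             hamming_distance(g1, g2) + hamming_distance(g2, g3) + 1e-12)
})

test_that("empirical p-values follow the add-one convention with ties", {
  expect_equal(empirical_pvalue(100, 1:99, "high"), 1 / 100)
  expect_equal(empirical_pvalue(-5, 1:99, "high"), 1)
  expect_equal(empirical_pvalue(4, c(1, 2, 3, 4, 4, 4, 4, 0, -1), "high"),
               5 / 10)
  expect_equal(empirical_pvalue(0, 1:9, "low"), 1 / 10)
  expect_error(empirical_pvalue(1, numeric(), "high"), "empty")
})

test_that("within-condition centering zeroes per-condition gene means", {
  spec <- two_condition_spec(n_samples = 10)
  sim <- simulate_two_conditions(spec, seed = 5)
  pooled <- expression_matrix(
    cbind(sim$expr_a$values, sim$expr_b$values),
    condition_of = c(sim$expr_a$condition_of, sim$expr_b$condition_of))
  centered <- center_within_condition(pooled)
  for (cond in c("A", "B")) {
    cols <- names(centered$condition_of)[centered$condition_of == cond]
    expect_equal(max(abs(rowMeans(centered$values[, cols]))), 0,
                 tolerance = 1e-12)
  }
  expect_error(center_within_condition(expression_matrix(pooled$values)),
               "condition labels")
})

test_that("null ensemble matches the reference density and is seeded", {
  spec <- two_condition_spec(n_samples = 25)
  sim <- simulate_two_conditions(spec, seed = 8)
  ref <- extract_skeleton(sim$expr_a, spec$genes)$skeleton
  ens <- build_null_ensemble(sim$expr_a, sim$expr_b, ref, n = 5, seed = 123)
  expect_length(ens$graphs, 5)
  for (g in ens$graphs) {
    expect_identical(n_edges(g), n_edges(ref$graph))
    expect_identical(g$nodes, ref$graph$nodes)
  }
  ens2 <- build_null_ensemble(sim$expr_a, sim$expr_b, ref, n = 5, seed = 123)
  expect_identical(ens$graphs, ens2$graphs)
  ens3 <- build_null_ensemble(sim$expr_a, sim$expr_b, ref, n = 2, seed = 124)
  expect_false(identical(ens$graphs[[1]], ens3$graphs[[1]]))
  # paired mode: pseudo-B graphs match the B reference's density
  ref_b <- extract_skeleton(sim$expr_b, spec$genes)$skeleton
  ens4 <- build_null_ensemble(sim$expr_a, sim$expr_b, ref, n = 3, seed = 9,
                              reference_b = ref_b)
  for (g in ens4$graphs_b) {
    expect_identical(n_edges(g), n_edges(ref_b$graph))
  }
  expect_identical(vapply(ens4$graphs, n_edges, integer(1)),
                   rep(n_edges(ref$graph), 3L))
})

test_that("identical condition data yields identical skeletons, Hamming 0", {
  spec <- two_condition_spec(n_samples = 25, rewire = NULL)
  sim <- simulate_expression(spec, seed = 31)
  cmp <- compare_conditions(sim$expr, sim$expr, spec$genes,
                            n_null = 5, seed = 2)
  expect_equal(cmp$results$hamming$observed, 0)
  expect_equal(cmp$results$jaccard$observed, 1)
  expect_equal(cmp$results$spectral$observed, 0)
  # difference tails point the right way per metric
  expect_equal(cmp$results$hamming$p_difference, cmp$results$hamming$p_high)
  expect_equal(cmp$results$jaccard$p_difference, cmp$results$jaccard$p_low)
})

test_that("metric subset flag restricts the report", {
  spec <- two_condition_spec(n_samples = 25, rewire = NULL)
  sim <- simulate_two_conditions(spec, seed = 77)
  cmp <- compare_conditions(sim$expr_a, sim$expr_b, spec$genes,
                            n_null = 3, seed = 4, metrics = "hamming")
  expect_named(cmp$results, "hamming")
  expect_identical(cmp$results$hamming$n_null, 3L)
})
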