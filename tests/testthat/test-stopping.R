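test_that("gene_mse: exact fits, intercept-only variance, saturated regime", {
  vals <- rbind(gA = c(1, 2, 3, 4, 5),
                gB = c(2, 4, 6, 8, 10),
                gC = c(5, 1, 4, 2, 3))
  colnames(vals) <- paste0("s", 1:5)
  expr <- expression_matrix(vals)
  g <- make_graph(c("gA", "gB", "gC"), "gA", "gB", 0.9)
  # gB = 2 * gA exactly while gA is a neighbor
  expect_equal(gene_mse(expr, g, "gB"), 0, tolerance = 1e-20)
  # isolated gene: population variance
  expr3 <- expression_matrix(rbind(gC = c(1, 2, 3)),
                             sample_ids = paste0("s", 1:3))
  iso <- weighted_graph("gC", matrix(0, 1, 1))
  expect_equal(gene_mse(expr3, iso, "gC"), 2 / 3)
  expect_error(gene_mse(expr, g, "nope"), "nope")
  # saturated regime (neighbors >= samples - 1) gives MSE 0
  sat_vals <- withr::with_seed(1, matrix(rnorm(5 * 4), 5, 4))
  dimnames(sat_vals) <- list(paste0("g", 1:5), paste0("s", 1:4))
  satg <- complete_graph(5)
  satg$nodes <- paste0("g", 1:5)
  dimnames(satg$weights) <- list(satg$nodes, satg$nodes)
  expect_equal(gene_mse(expression_matrix(sat_vals), satg, "g1"), 0,
               tolerance = 1e-20)
})

test_that("gene_mse approaches sigma^2 (n-p-1)/n for a linear model", {
  n <- 5000
  sigma <- 0.5
  vals <- withr::with_seed(21, {
    x <- matrix(rnorm(3 * n), 3, n)
    y <- colSums(x) + rnorm(n, sd = sigma)
    rbind(x, y)
  })
  dimnames(vals) <- list(c("n1", "n2", "n3", "target"), paste0("s", 1:n))
  expr <- expression_matrix(vals)
  g <- make_graph(c("n1", "n2", "n3", "target"),
                  "target", "n1", 1, "target", "n2", 1, "target", "n3", 1)
  expected <- sigma^2 * (n - 3 - 1) / n
  expect_equal(gene_mse(expr, g, "target"), expected, tolerance = 0.05)
})

test_that("mse_trajectory checkpoints, determinism, and stride handling", {
  spec <- two_block_bridge_spec(n_samples = 60)
  sim <- simulate_expression(spec, seed = 14)
  g <- build_complete_graph(sim$expr, spec$genes)
  tr <- greedy_sparsify(g, stop = "fragmentation")
  cv <- mse_trajectory(sim$expr, tr, stride = 1L)
  expect_identical(cv$step, c(0L, seq_len(nrow(tr))))
  expect_true(all(diff(cv$fraction_removed) > 0))
  expect_true(all(cv$median_mse >= 0))
  expect_identical(mse_trajectory(sim$expr, tr, stride = 1L), cv)
  # incremental update equals recomputation from scratch at a checkpoint
  mid <- nrow(tr) %/% 2
  g_mid <- graph_at_step(tr, mid)
  recomputed <- vapply(g$nodes,
                       function(gn) gene_mse(sim$expr, g_mid, gn), numeric(1))
  expect_equal(unname(attr(cv, "per_gene")[, as.character(mid)]),
               unname(recomputed), tolerance = 1e-12)
  # stride == number of steps: checkpoints at 0 and the end only
  cv2 <- mse_trajectory(sim$expr, tr, stride = nrow(tr))
  expect_identical(cv2$step, c(0L, nrow(tr)))
})

synthetic_curve <- function(fracs, junction, slope = 10, base = 1,
                            noise_sd = 0, seed = 1, frag_step = NA_integer_) {
  y <- base + pmax(fracs - junction, 0) * slope
  if (noise_sd > 0) {
    y <- y + withr::with_seed(seed, rnorm(length(y), sd = noise_sd))
  }
  structure(data.frame(step = seq_along(fracs) - 1L,
                       fraction_removed = fracs, median_mse = y),
            fragmentation_step = frag_step, n_edges0 = length(fracs),
            class = c("mse_curve", "data.frame"))
}

test_that("find_elbow recovers an exact piecewise-linear junction", {
  fracs <- seq(0, 0.9, by = 0.03)
  cv <- synthetic_curve(fracs, junction = 0.6)
  elbow <- find_elbow(cv)
  expect_equal(cv$fraction_removed[cv$step == elbow], 0.6, tolerance = 1e-9)
})

test_that("find_elbow tie rule and fallback", {
  # perfectly straight line: every breakpoint ties; smallest k wins
  fracs <- seq(0, 0.5, length.out = 12)
  cv <- synthetic_curve(fracs, junction = 0, slope = 2, base = 0.1)
  expect_identical(find_elbow(cv), 2L)  # k = 3 -> checkpoint index 3, step 2
  # fewer than 6 checkpoints: warn and fall back to last safe step
  short <- synthetic_curve(seq(0, 0.2, length.out = 5), junction = 0.1)
  expect_warning(e <- find_elbow(short), "fewer than 6")
  expect_identical(e, 4L)
  # checkpoints at/after fragmentation are excluded from the fit
  fracs2 <- seq(0, 0.9, by = 0.03)
  cv2 <- synthetic_curve(fracs2, junction = 0.45, frag_step = 26L)
  elbow2 <- find_elbow(cv2)
  expect_lt(elbow2, 26L)
  expect_equal(cv2$fraction_removed[cv2$step == elbow2], 0.45,
               tolerance = 1e-9)
})

test_that("noisy elbows are recovered within +/-2 checkpoints", {
  fracs <- seq(0, 0.9, by = 0.03)
  junction <- 0.6
  true_idx <- which.min(abs(fracs - junction))
  hits <- 0L
  for (s in 1:50) {
    # sigma = 1% of the curve's range (10 * (0.9 - 0.6) = 3)
    cv <- synthetic_curve(fracs, junction, noise_sd = 0.03, seed = s)
    idx <- which(cv$step == find_elbow(cv))
    if (abs(idx - true_idx) <= 2) hits <- hits + 1L
  }
  expect_gte(hits, 45L)
})

test_that("extract_skeleton keeps the weak bridge and stays connected", {
  spec <- two_block_bridge_spec(n_samples = 120)
  sim <- simulate_expression(spec, seed = 33)
  res <- extract_skeleton(sim$expr, gene_set("blocks", spec$genes))
  skel <- res$skeleton
  expect_true(is_connected(skel$graph))
  expect_gt(skel$spectral_gap, 0)
  expect_gt(skel$graph$weights["g1", "g11"], 0)  # the sole cross-block tie
  expect_lt(skel$elbow_step, fragmentation_step(res$trace))
  # deterministic end-to-end
  res2 <- extract_skeleton(sim$expr, gene_set("blocks", spec$genes))
  expect_identical(res2$skeleton$graph$weights, skel$graph$weights)
})

test_that("a star-like graph cannot be sparsified: skeleton == complete graph", {
  # hub drives every leaf; leaves are conditionally independent
  vals <- withr::with_seed(55, {
    hub <- rnorm(80)
    rbind(hub = hub,
          l1 = 0.9 * hub + 0.45 * rnorm(80),
          l2 = 0.9 * hub + 0.45 * rnorm(80),
          l3 = 0.9 * hub + 0.45 * rnorm(80))
  })
  colnames(vals) <- paste0("s", 1:80)
  expr <- expression_matrix(vals)
  g <- build_complete_graph(expr, rownames(vals))
  # prune to an actual star so any removal fragments
  gstar <- threshold_sparsify(g, max(g$weights[c("l1", "l2", "l3"),
                                               c("l1", "l2", "l3")]) + 0.01)
  tr <- greedy_sparsify(gstar, stop = "fragmentation")
  expect_identical(nrow(tr), 0L)
  skel <- skeleton(gstar, 0L, n_edges(gstar))
  expect_identical(n_edges(skel$graph), n_edges(gstar))
  expect_equal(skel$sparsification_fraction, 0)
})

test_that("removing a designated generating edge strictly increases that gene's MSE", {
  n <- 1000
  vals <- withr::with_seed(66, {
    a <- rnorm(n); b <- rnorm(n); c <- rnorm(n)
    y <- a + b + c + rnorm(n, sd = 0.3)
    rbind(a = a, b = b, c = c, y = y)
  })
  colnames(vals) <- paste0("s", 1:n)
  expr <- expression_matrix(vals)
  g <- make_graph(c("a", "b", "c", "y"),
                  "y", "a", 0.5, "y", "b", 0.5, "y", "c", 0.5,
                  "a", "b", 0.1)
  full <- gene_mse(expr, g, "y")
  dropped <- gene_mse(expr, drop_edge(g, 4L, 1L), "y")
  expect_gt(dropped, full)
})

test_that("skeleton constructor enforces connectivity and positive gap", {
  disc <- make_graph(c("a", "b", "c", "d"), "a", "b", 1, "c", "d", 1)
  expect_error(skeleton(disc), "single component")
})
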