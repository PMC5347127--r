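test_that("BH adjustment reproduces the step-up procedure", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04, 0.05)),
               c(0.04, 0.04, 0.05, 0.05))
  expect_equal(bh_adjust(rep(0.03, 7)), rep(0.03, 7))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.1, NA)), "NA")
  set.seed(41)
  for (i in 1:1000) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_adjust(p), bh_stepup(p), tolerance = 1e-12)
  }
})

test_that("feature screen flags planted shifts and respects the null", {
  # a feature identical across groups is never significant
  x <- tiny_matrix(10L, 3L, seed = 2)
  x[, 2] <- rep(c(5, 6, 7, 8, 9), 2)
  lab <- sample_labels(rep(c("A", "B"), each = 5), paste0("s", 1:10))
  sc <- feature_screen(x, lab)
  expect_equal(sc$p_raw[2], 1)
  expect_false(sc$significant[2])
  expect_equal(sc$median_diff[2], 0)
  # strong planted shift at n=20/20 is caught
  g <- generate_planted(scenario_preset("and_gate", seed = 55))
  sc2 <- feature_screen(g$matrix, g$labels)
  strong <- startsWith(sc2$feature, "b1_")
  expect_true(all(sc2$significant[strong]))
  expect_true(all(sc2$median_diff[strong] < 0))  # B is shifted up; A - B < 0
  # adjusted >= raw always
  expect_true(all(sc2$p_adjusted >= sc2$p_raw - 1e-12))
})

test_that("P-value network keeps only significant, well-correlated features", {
  g <- generate_planted(scenario_preset("and_gate", seed = 14))
  sc <- feature_screen(g$matrix, g$labels)
  pv <- build_pvalue_network(g$matrix, g$labels, 0.5, screen = sc)
  expect_true(pv$exists)
  expect_true(all(pv$nodes$feature %in% sc$feature[sc$significant]))
  # all edges are correlations above the cut-off among significant features
  cc <- pearson_matrix(g$matrix[, sc$feature[sc$significant], drop = FALSE])
  for (k in seq_len(nrow(pv$edges)))
    expect_gte(abs(cc[pv$edges$source[k], pv$edges$target[k]]), 0.5)
})

test_that("fewer than two significant features yields a no-network object", {
  g <- generate_planted(scenario_preset("null", seed = 4))
  pv <- build_pvalue_network(g$matrix, g$labels, 0.5)
  expect_false(pv$exists)
  expect_match(pv$reason, "significant")
  pm <- build_pvalue_mi_network(g$matrix, g$labels, 0.5)
  expect_false(pm$exists)
})

test_that("match_node_count_cutoff finds the closest-from-above cut-off", {
  # engineered: 6 nodes up to 0.6, 4 nodes at 0.61..0.7, 2 above
  edges <- list(list("a", "b", 0.95), list("c", "d", 0.7),
                list("c", "e", 0.6), list("d", "f", 0.6))
  w <- weights_from_edges(letters[1:6], edges)
  expect_equal(match_node_count_cutoff(w, 6), 0.6)
  expect_equal(match_node_count_cutoff(w, 4), 0.7)
  expect_equal(match_node_count_cutoff(w, 2), 0.95)
  expect_error(match_node_count_cutoff(w, 10), "exceeds")
  # monotone: higher target -> lower or equal cut-off
  cuts <- vapply(c(2, 4, 6), function(t) match_node_count_cutoff(w, t),
                 numeric(1))
  expect_true(all(diff(cuts) <= 0))
})

test_that("Gaussian MI is even, increasing in |r|, and capped at |r| = 1", {
  expect_equal(gaussian_mi(0), 0)
  expect_equal(gaussian_mi(0.9), -0.5 * log(1 - 0.81))
  expect_equal(gaussian_mi(0.9), 0.83034, tolerance = 1e-4)
  expect_equal(gaussian_mi(-0.7), gaussian_mi(0.7))
  rs <- seq(0, 0.99, by = 0.01)
  expect_true(all(diff(gaussian_mi(rs)) > 0))
  expect_warning(capped <- gaussian_mi(1), "capped")
  expect_true(is.finite(capped))
  expect_error(gaussian_mi(1.5), "<= 1")
})

test_that("CLR scores match the per-row z-score oracle", {
  mi <- matrix(c(0, 2, 1,
                 2, 0, 4,
                 1, 4, 0), 3, 3, byrow = TRUE,
               dimnames = list(letters[1:3], letters[1:3]))
  got <- clr_scores(mi)
  # hand z-scores: row a over (2,1): mean 1.5 sd sqrt(0.5)
  za_ab <- max(0, (2 - 1.5) / sqrt(0.5))
  # row b over (2,4): mean 3, sd sqrt(2)
  zb_ab <- max(0, (2 - 3) / sqrt(2))
  expect_equal(got["a", "b"], sqrt(za_ab^2 + zb_ab^2))
  expect_true(isSymmetric(got))
  expect_equal(diag(got), setNames(rep(0, 3), letters[1:3]))
  # constant MI -> all zero; shift invariance
  const <- matrix(1, 3, 3); diag(const) <- 0
  expect_equal(clr_scores(const), matrix(0, 3, 3))
  expect_equal(clr_scores(mi + 10 - diag(10, 3)), got)
})

test_that("P-value MI network nodes are screened features; tables symmetric", {
  g <- generate_planted(scenario_preset("lipidomics_like", seed = 9))
  sc <- feature_screen(g$matrix, g$labels)
  pm <- build_pvalue_mi_network(g$matrix, g$labels, 0.6, screen = sc)
  expect_true(pm$exists)
  expect_true(all(pm$nodes$feature %in% sc$feature[sc$significant]))
  expect_true(all(pm$edges$source < pm$edges$target))
})

test_that("venn comparison counts node and edge overlaps", {
  wA <- weights_from_edges(c("a", "b", "c"),
                           list(list("a", "b", 0.9), list("b", "c", 0.8)))
  wB <- weights_from_edges(c("b", "c", "d"),
                           list(list("b", "c", 0.8), list("c", "d", 0.7)))
  vA <- c(a = 1, b = 1, c = 1); vB <- c(b = 1, c = 1, d = 1)
  nA <- threshold_network(make_pcc(wA, vA), 0.5)
  nB <- threshold_network(make_pcc(wB, vB), 0.5)
  vc <- venn_compare(nA, nB)
  expect_equal(vc$nodes, c(only_A = 1, shared = 2, only_B = 1))
  expect_equal(vc$edges, c(only_A = 1, shared = 1, only_B = 1))
  same <- venn_compare(nA, nA)
  expect_equal(same$nodes[["only_A"]], 0)
  expect_equal(same$edges[["shared"]], 2)
  # 4-way patterns
  vc4 <- venn_compare(A = nA, B = nB, C = nA, D = nB)
  expect_equal(sum(vc4$nodes), 4)  # a, b, c, d
  expect_equal(unname(vc4$nodes[["1111"]]), 2)  # b and c everywhere
})

test_that("under the global null the screen rarely finds anything", {
  hits <- 0L
  for (s in 1:200) {
    g <- generate_planted(planted_design(10, n_noise = 40, seed = 500 + s))
    sc <- feature_screen(g$matrix, g$labels)
    if (any(sc$significant)) hits <- hits + 1L
  }
  expect_lte(hits / 200, 0.10)
})
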