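test_that("heuristic normalization matches direct evaluation and keeps order", {
  nl <- normalize_loadings(c(0.5, -0.5, 0.5, -0.5))
  expect_equal(abs(nl$v_star), rep(log10(2), 4))
  expect_equal(sign(nl$v_star), c(1, -1, 1, -1))

  nl2 <- normalize_loadings(c(0.9, 0.1))
  expect_equal(nl2$mean_abs, 0.5)
  expect_equal(nl2$v_star, c(log10(1 + 0.9 / 0.5), log10(1 + 0.1 / 0.5)),
               tolerance = 1e-12)
  expect_equal(nl2$v_star, c(0.44716, 0.07918), tolerance = 1e-4)

  expect_error(normalize_loadings(c(0, 0)), "zero")

  # |v_star| strictly increasing in |v_raw|
  set.seed(2)
  v <- rnorm(50)
  nl3 <- normalize_loadings(v)
  o <- order(abs(v))
  expect_true(all(diff(abs(nl3$v_star)[o]) > 0))
  expect_equal(sign(nl3$v_star), sign(v))
})

test_that("scaling puts the extreme loading at +/-1 and is idempotent", {
  nl <- scale_loadings(normalize_loadings(c(0.9, 0.1)))
  expect_equal(nl$v_new, c(1, 0.17707), tolerance = 1e-4)
  expect_equal(max(abs(nl$v_new)), 1)
  sym <- process_loadings(c(0.3, -0.3, 0.3))
  expect_setequal(unique(sym$v_new), c(1, -1))
  twice <- scale_loadings(process_loadings(c(0.2, -0.7, 0.05)))
  expect_equal(twice$v_new, process_loadings(c(0.2, -0.7, 0.05))$v_new)
})

test_that("pearson matrix matches the nested-loop oracle and handles edge cases", {
  x <- tiny_matrix(5L, 4L, seed = 8)
  expect_equal(pearson_matrix(x), cor_loop(x), tolerance = 1e-12)
  # duplicated feature and negated feature
  y <- omic_matrix(cbind(a = x[, 1], b = x[, 1], c = -x[, 1]))
  cc <- pearson_matrix(y)
  expect_equal(cc["a", "b"], 1)
  expect_equal(cc["a", "c"], -1)
  # constant feature -> zero correlations, warning
  z <- omic_matrix(cbind(a = x[, 1], k = rep(2, 5)))
  expect_warning(cz <- pearson_matrix(z), "constant")
  expect_equal(cz["a", "k"], 0)
  expect_equal(cz["k", "k"], 1)
})

test_that("edge fusion equals the scalar sign*min oracle", {
  expect_equal(pccorr_edge(0.8, 1.0, 0.6), 0.6)
  expect_equal(pccorr_edge(-0.9, 0.95, 0.85), -0.85)
  expect_equal(pccorr_edge(0, 0.7, 0.9), 0)
  expect_error(pccorr_edge(1.2, 0.5, 0.5), "\\[-1, 1\\]")
  set.seed(7)
  for (i in 1:200) {
    tri <- runif(3, -1, 1)
    expect_identical(pccorr_edge(tri[1], tri[2], tri[3]),
                     edge_oracle(tri[1], tri[2], tri[3]))
  }
})

test_that("the PC-corr matrix obeys the min bound with equality", {
  x <- tiny_matrix(10L, 6L, seed = 3)
  nl <- process_loadings(fit_pca(x, "centered")$loadings[, 1])
  pcc <- build_pccorr_matrix(x, nl)
  w <- pcc$weights
  expect_true(isSymmetric(w))
  expect_equal(diag(w), setNames(rep(0, 6), colnames(x)))
  for (i in 1:5) for (j in (i + 1):6) {
    expect_equal(w[i, j],
                 edge_oracle(pcc$corr[i, j], nl$v_new[i], nl$v_new[j]))
  }
  # zero loading annihilates its row/column
  nl0 <- nl
  nl0$v_new[2] <- 0
  pcc0 <- build_pccorr_matrix(x, nl0)
  expect_equal(unname(pcc0$weights[2, ]), rep(0, 6))
})

test_that("feature permutation permutes the PC-corr matrix consistently", {
  x <- tiny_matrix(9L, 5L, seed = 13)
  nl <- process_loadings(fit_pca(x, "centered")$loadings[, 1])
  pcc <- build_pccorr_matrix(x, nl)
  perm <- c(3, 1, 5, 2, 4)
  nlp <- nl
  nlp$v_raw <- nl$v_raw[perm]; nlp$v_star <- nl$v_star[perm]
  nlp$v_new <- nl$v_new[perm]
  pccp <- build_pccorr_matrix(x[, perm], nlp)
  expect_equal(pccp$weights, pcc$weights[perm, perm])
})

test_that("thresholding keeps strong edges, drops singletons, is monotone", {
  w <- weights_from_edges(c("A", "B", "C", "E"),
                          list(list("A", "B", 0.7), list("B", "C", 0.4),
                               list("C", "E", 0.2)))
  v <- c(A = 1, B = 0.8, C = 0.5, E = 0.3)
  net <- threshold_network(make_pcc(w, v), 0.5)
  expect_setequal(edge_keys(net$edges), "A|B")
  expect_setequal(net$nodes$feature, c("A", "B"))
  expect_warning(empty <- threshold_network(make_pcc(w, v), 1.0), "no edge")
  expect_equal(nrow(empty$edges), 0L)
  # monotonicity over a random matrix
  x <- tiny_matrix(12L, 8L, seed = 21)
  pcc <- build_pccorr_matrix(x, process_loadings(
    fit_pca(x, "centered")$loadings[, 1]))
  prev <- character()
  for (co in c(0.9, 0.7, 0.5, 0.3, 0.1)) {
    keys <- edge_keys(suppressWarnings(
      threshold_network(pcc, co))$edges)
    expect_true(all(prev %in% keys))
    prev <- keys
  }
  expect_error(threshold_network(pcc, 0), "\\(0, 1\\]")
})

test_that("node attributes carry group, colour gradient and degree", {
  g <- generate_planted(scenario_preset("and_gate", seed = 30))
  res <- pc_corr(g$matrix, g$labels, cutoff = 0.5)
  nodes <- res$network$nodes
  expect_true(all(nodes$group %in% c("A", "B")))
  expect_true(all(grepl("^#[0-9A-F]{6}$", nodes$color)))
  expect_equal(sort(unique(nodes$degree)),
               sort(unique(as.integer(table(c(res$network$edges$source,
                                              res$network$edges$target))))))
  # block 1 is shifted up in group B, so its nodes belong to B
  b1 <- nodes$feature[startsWith(nodes$feature, "b1_")]
  expect_true(all(nodes$group[nodes$feature %in% b1] == "B"))
})

test_that("frustration definition, symmetry and empty-network convention", {
  w <- weights_from_edges(c("a", "b", "c"),
                          list(list("a", "b", 0.6),   # + edge, same sign: ok
                               list("a", "c", 0.6),   # + edge, opposite: frustrated
                               list("b", "c", -0.6))) # - edge, opposite: ok
  v <- c(a = 1, b = 0.9, c = -0.8)
  net <- threshold_network(make_pcc(w, v), 0.5)
  fr <- compute_frustration(net)
  expect_equal(fr$fraction, 1 / 3)
  expect_equal(edge_keys(fr$frustrated), "a|c")
  # flipping every node sign leaves the fraction unchanged (the edge is
  # frustrated iff sign(w) != sign(v_i * v_j), and products are invariant)
  netn <- threshold_network(make_pcc(w, -v), 0.5)
  expect_equal(compute_frustration(netn)$fraction, 1 / 3)
  # gauge symmetry: flipping one node together with all its incident
  # edges leaves the fraction unchanged
  wg <- w
  wg["c", ] <- -wg["c", ]; wg[, "c"] <- -wg[, "c"]
  vg <- v; vg["c"] <- -vg["c"]
  netg <- threshold_network(make_pcc(wg, vg), 0.5)
  expect_equal(compute_frustration(netg)$fraction, 1 / 3)
  empty <- suppressWarnings(threshold_network(make_pcc(w, v), 0.99))
  expect_equal(compute_frustration(empty)$fraction, 0)
})

test_that("drop policy removes rare frustration and refuses above 5%", {
  # 30 edges, exactly one frustrated (3.3%)
  nodes <- c(paste0("p", 1:8), "q", "z")
  edges <- list()
  for (i in 1:7) for (j in (i + 1):8)
    edges <- c(edges, list(list(paste0("p", i), paste0("p", j), 0.8)))
  edges <- c(edges, list(list("p1", "z", 0.8),   # frustrated (z negative)
                         list("p2", "z", -0.8))) # consistent
  w <- weights_from_edges(nodes, edges)
  v <- setNames(c(rep(1, 8), 0.9, -1), nodes)
  net0 <- threshold_network(make_pcc(w, v), 0.5)
  expect_equal(nrow(net0$edges), 30L)
  dropped <- resolve_frustration(make_pcc(w, v), 0.5, "drop")
  expect_equal(nrow(dropped$edges), 29L)
  expect_equal(dropped$metadata$final_frustration, 0)
  expect_equal(edge_keys(dropped$metadata$removed_edges), "p1|z")
  # 1/3 frustrated -> refusal
  w3 <- weights_from_edges(c("a", "b", "c"),
                           list(list("a", "b", 0.6), list("a", "c", 0.6),
                                list("b", "c", -0.6)))
  v3 <- c(a = 1, b = 0.9, c = -0.8)
  ref <- resolve_frustration(make_pcc(w3, v3), 0.5, "drop")
  expect_true(isTRUE(ref$metadata$refused))
  expect_equal(nrow(ref$edges), 3L)  # untouched
})

test_that("raise policy steps the cut-off to the engineered frustration-free level", {
  w <- weights_from_edges(c("A", "B", "C", "D"),
                          list(list("A", "B", 0.9),
                               list("C", "D", 0.715),  # frustrated, dies at 0.72
                               list("A", "D", 0.75)))
  v <- c(A = 1, B = 0.9, C = -0.95, D = 0.8)
  raised <- resolve_frustration(make_pcc(w, v), 0.6, "raise")
  expect_equal(raised$metadata$final_cutoff, 0.72)
  expect_equal(raised$metadata$final_frustration, 0)
  expect_setequal(edge_keys(raised$edges), c("A|B", "A|D"))
  # frustration-free network is a fixed point for every policy
  wok <- weights_from_edges(c("A", "B"), list(list("A", "B", 0.9)))
  vok <- c(A = 1, B = 1)
  for (pol in c("report", "drop", "raise")) {
    out <- resolve_frustration(make_pcc(wok, vok), 0.5, pol)
    expect_equal(nrow(out$edges), 1L)
  }
})
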