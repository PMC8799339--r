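test_that("generators are pure functions of parameters and seed", {
  g1 <- gen_network(200, "scale_free", param = 2, seed = 7)
  g2 <- gen_network(200, "scale_free", param = 2, seed = 7)
  el <- function(g) paste(igraph::as_edgelist(g)[, 1], igraph::as_edgelist(g)[, 2])
  expect_identical(el(g1), el(g2))
  expect_identical(igraph::E(g1)$weight, igraph::E(g2)$weight)
  g3 <- gen_network(200, "scale_free", param = 2, seed = 8)
  expect_false(identical(el(g1), el(g3)))
  # the caller's RNG stream is left untouched
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(gen_network(50, seed = 1)); after <- runif(1)
  expect_identical(before, after)
})

test_that("generated networks are connected, simple, and confidence-weighted", {
  for (model in c("scale_free", "erdos_renyi")) {
    g <- gen_network(100, model, param = if (model == "scale_free") 2 else 0.08,
                     seed = 5)
    expect_true(igraph::is_connected(g))
    expect_false(igraph::any_multiple(g) || igraph::any_loop(g))
    expect_true(all(igraph::E(g)$weight >= 0.4 & igraph::E(g)$weight <= 1))
    expect_gte(igraph::vcount(g), 90)
  }
  # p = 1 gives the complete graph
  full <- gen_network(10, "erdos_renyi", param = 1, seed = 1)
  expect_equal(igraph::ecount(full), choose(10, 2))
  expect_error(gen_network(2, "scale_free"), "n_nodes")
  expect_error(gen_network(50, "scale_free", param = 0.5), "positive integer")
})

test_that("scale-free degree sequences are heavy-tailed across seeds", {
  ratios <- vapply(1:50, function(s) {
    d <- igraph::degree(gen_network(200, "scale_free", param = 2, seed = s))
    max(d) / stats::median(d)
  }, 0)
  expect_true(all(ratios >= 3))
})

test_that("database-set generation hits the requested overlap", {
  universe <- sprintf("G%06d", 1:500)
  same <- gen_db_sets(universe, c(40, 40, 40), overlap = 1, seed = 1)
  expect_equal(same[[1]], same[[2]], ignore_attr = TRUE)
  expect_equal(same[[2]], same[[3]], ignore_attr = TRUE)
  disj <- gen_db_sets(universe, c(30, 40, 50), overlap = 0, seed = 2)
  expect_length(intersect(disj[[1]], disj[[2]]), 0)
  expect_length(intersect(disj[[1]], disj[[3]]), 0)
  half <- gen_db_sets(universe, c(60, 60, 60), overlap = 0.5, seed = 3)
  jac <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    expect_true(abs(jac(half[[pair[1]]], half[[pair[2]]]) - 0.5) <= 0.1)
  }
  expect_error(gen_db_sets(universe[1:50], c(30, 40, 50), 0, seed = 1),
               "infeasible")
})

test_that("component classes satisfy their distance constraints by construction", {
  inst <- gen_instance(seed = 6, n_direct = 5)
  d <- igraph::distances(inst$network, to = inst$key_set, weights = NA)
  mind <- apply(d, 1, min)
  for (i in seq_len(nrow(inst$truth))) {
    targets <- inst$components[[inst$truth$component_id[i]]]
    switch(inst$truth$class[i],
      proximal = expect_true(all(mind[targets] == 1)),
      distal = expect_true(all(mind[targets] >= 3)),
      direct = expect_true(any(targets %in% inst$key_set))
    )
  }
  # no distal components can be built when no node is far enough
  clique <- gen_hub_network(n_hubs = 8, n_periphery = 10, seed = 1)$network
  expect_error(
    gen_components(clique, igraph::V(clique)$name[1:8], 0, 5,
                   targets_per_component = 3, seed = 1),
    "insufficient distal")
})

test_that("n_distal = 0 keeps every component within one hop of the key set", {
  inst <- gen_instance(seed = 7, n_proximal = 8, n_distal = 0)
  d <- igraph::distances(inst$network, to = inst$key_set, weights = NA)
  mind <- apply(d, 1, min)
  for (targets in inst$components) expect_true(all(mind[targets] <= 1))
})

test_that("planted-hub networks put hubs at the top of every indicator", {
  hg <- gen_hub_network(n_hubs = 10, n_periphery = 190, seed = 9)
  x <- indicator_matrix(hg$network)
  for (ind in c("degree", "closeness", "betweenness", "pagerank")) {
    top10 <- rownames(x)[order(-x[, ind])][1:10]
    expect_setequal(top10, hg$hubs)
  }
  # eccentricity: hubs are the most central (smallest) nodes
  expect_true(max(x[hg$hubs, "eccentricity"]) <= min(x[setdiff(rownames(x), hg$hubs), "eccentricity"]))
})
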