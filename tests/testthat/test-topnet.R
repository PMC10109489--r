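test_that("node weights follow the fold-change / reciprocal convention", {
  fc <- c(g1 = 4, g2 = 1, g3 = 0.25)
  expect_equal(compute_node_weights(fc, "active"),
               c(g1 = 4, g2 = 1, g3 = 0.25))
  expect_equal(compute_node_weights(fc, "repressed"),
               c(g1 = 0.25, g2 = 1, g3 = 4))
  expect_error(compute_node_weights(c(g1 = -1), "active"), "g1")
  expect_error(compute_node_weights(c(bad = 0), "repressed"), "bad")
})

test_that("edge weights are inverse square roots of node-weight products", {
  expect_equal(compute_edge_weight(1, 1), 1)
  expect_equal(compute_edge_weight(4, 4), 0.25)
  expect_equal(compute_edge_weight(2, 8), 0.25)   # product invariance
  expect_equal(compute_edge_weight(3, 7), compute_edge_weight(7, 3))
  expect_error(compute_edge_weight(0, 1), "positive")
  # monotonicity: raising either endpoint weight strictly lowers the edge
  set.seed(31)
  w1 <- runif(200, 0.1, 10); w2 <- runif(200, 0.1, 10)
  expect_true(all(compute_edge_weight(w1 * 1.5, w2) <
                    compute_edge_weight(w1, w2)))
  expect_true(all(compute_edge_weight(w1, w2 * 1.5) <
                    compute_edge_weight(w1, w2)))
})

test_that("condition networks drop unexpressed nodes and derive edge weights exactly", {
  ids <- c("a", "b", "c", "d")
  g <- igraph::graph_from_edgelist(
    cbind(c("a", "b", "c"), c("b", "c", "d")), directed = TRUE)
  fc <- c(a = 4, b = 1, c = 2.5)   # d has no expression
  expect_message(cn <- condition_network(g, fc, "active"), "dropped")
  expect_identical(cn$dropped, "d")
  el <- igraph::as_edgelist(cn$graph)
  w <- igraph::V(cn$graph)$weight
  names(w) <- igraph::V(cn$graph)$name
  expect_equal(igraph::E(cn$graph)$weight,
               1 / sqrt(w[el[, 1]] * w[el[, 2]]), ignore_attr = TRUE)
})

test_that("active/repressed duality: swapping groups swaps the networks", {
  pe <- data.frame(gene = sprintf("g%04d", 1:5), group = "test", log2fc = 1.5)
  sim <- small_counts(seed = 12, n_genes = 40, planted = pe)
  g <- simulate_network(simulation_config(n_genes = 40, network_nodes = 40,
                                          seed = 12))
  ab <- wald_test(sim$counts, "test", "ref")
  ba <- wald_test(sim$counts, "ref", "test")
  fc_ab <- setNames(2^ab$log2fc, ab$gene)
  fc_ba <- setNames(2^ba$log2fc, ba$gene)
  act_swap <- condition_network(g, fc_ba, "active")
  rep_orig <- condition_network(g, fc_ab, "repressed")
  expect_equal(igraph::V(act_swap$graph)$weight,
               igraph::V(rep_orig$graph)$weight, tolerance = 1e-12)
  expect_equal(igraph::E(act_swap$graph)$weight,
               igraph::E(rep_orig$graph)$weight, tolerance = 1e-12)
})

test_that("a single edge yields a single one-edge path record", {
  cn <- as_cnet(data.frame(source = "u", target = "v", weight = 0.3))
  ps <- shortest_paths_all_pairs(cn)
  expect_equal(nrow(ps), 1)
  expect_equal(ps$cost, 0.3)
  expect_equal(ps$n_edges, 1)
  expect_equal(ps$normalized_cost, 0.3)
  expect_identical(ps$path, "u|v")
})

test_that("Dijkstra paths match exhaustive enumeration on random graphs", {
  for (s in 1:30) {
    el <- random_test_graph(n = sample(4:8, 1), seed = 100 + s)
    if (!nrow(el)) next
    cn <- as_cnet(el)
    ps <- shortest_paths_all_pairs(cn)
    for (i in seq_len(nrow(ps))) {
      oracle <- enumerate_shortest_path(el, ps$source[i], ps$target[i])
      expect_equal(ps$cost[i], oracle$cost, tolerance = 1e-9)
      expect_identical(ps$path[i], paste(oracle$path, collapse = "|"))
    }
    # every reachable ordered pair is present exactly once
    g <- cn$graph
    D <- igraph::distances(g, mode = "out")
    expect_equal(nrow(ps), sum(is.finite(D)) - igraph::vcount(g))
  }
})

test_that("equal-cost ties break toward the lexicographically smaller sequence", {
  el <- data.frame(source = c("s", "s", "x", "b"),
                   target = c("x", "b", "t", "t"),
                   weight = c(0.2, 0.2, 0.3, 0.3))
  ps <- shortest_paths_all_pairs(as_cnet(el))
  st <- ps[ps$source == "s" & ps$target == "t", ]
  expect_identical(st$path, "s|b|t")
})

test_that("path ranking is deterministic and order-independent", {
  el <- random_test_graph(7, seed = 77)
  ps <- shortest_paths_all_pairs(as_cnet(el))
  r1 <- rank_paths(ps)
  shuffled <- ps[sample(nrow(ps)), ]
  attr(shuffled, "nodes") <- attr(ps, "nodes")
  r2 <- rank_paths(shuffled)
  expect_identical(r1$path, r2$path)
  expect_true(!is.unsorted(r1$normalized_cost))
  # all-equal costs fall back to lexicographic sequence order
  eq <- data.frame(source = c("a", "b"), target = c("b", "c"),
                   cost = c(0.5, 0.5), n_edges = c(1L, 1L),
                   normalized_cost = c(0.5, 0.5),
                   path = c("b|c", "a|b")[c(2, 1)])
  eq$path <- c("b|c", "a|b")
  r3 <- rank_paths(eq)
  expect_identical(r3$path, c("a|b", "b|c"))
})

test_that("top-path selection by fraction and threshold behaves as specified", {
  fake <- data.frame(source = "a", target = "b", cost = seq_len(1000) / 100,
                     n_edges = 1L, normalized_cost = seq_len(1000) / 100,
                     path = sprintf("a|b%04d", 1:1000))
  ranked <- rank_paths(fake)
  expect_equal(nrow(select_top_paths(ranked, fraction = 1.0)), 1000)
  expect_equal(nrow(select_top_paths(ranked, fraction = 0.005)), 5)
  expect_error(select_top_paths(ranked, fraction = 0), "fraction")
  expect_warning(sel <- select_top_paths(ranked, threshold = 0.001),
                 "no paths")
  expect_equal(nrow(sel), 0)
  expect_equal(nrow(select_top_paths(ranked, threshold = 0.055)), 5)
})

test_that("rescaling all node weights leaves path ranks unchanged", {
  pe <- data.frame(gene = sprintf("g%04d", 1:6), group = "test", log2fc = 2)
  sim <- small_counts(seed = 14, n_genes = 30, planted = pe)
  g <- simulate_network(simulation_config(n_genes = 30, network_nodes = 30,
                                          seed = 14))
  res <- wald_test(sim$counts, "test", "ref")
  fc <- setNames(2^res$log2fc, res$gene)
  base <- rank_paths(shortest_paths_all_pairs(condition_network(g, fc, "active")))
  for (cc in c(0.1, 10)) {
    cn <- condition_network(g, fc, "active")
    igraph::V(cn$graph)$weight <- igraph::V(cn$graph)$weight * cc
    el <- igraph::as_edgelist(cn$graph, names = FALSE)
    igraph::E(cn$graph)$weight <-
      compute_edge_weight(igraph::V(cn$graph)$weight[el[, 1]],
                          igraph::V(cn$graph)$weight[el[, 2]])
    scaled <- rank_paths(shortest_paths_all_pairs(cn))
    expect_identical(scaled$path, base$path)
    # edge weights scale as 1/c, hence so does every path cost
    expect_equal(scaled$cost, base$cost / cc, tolerance = 1e-9)
  }
})

test_that("permutation threshold is seeded and exposes planted structure", {
  pe <- data.frame(gene = sprintf("g%04d", 1:8), group = "test", log2fc = 3)
  sim <- small_counts(seed = 15, n_genes = 40, planted = pe)
  g <- simulate_network(simulation_config(n_genes = 40, network_nodes = 40,
                                          seed = 15))
  res <- wald_test(sim$counts, "test", "ref")
  fc <- setNames(2^res$log2fc, res$gene)
  cn <- condition_network(g, fc, "active")
  thr1 <- permutation_threshold(cn, k = 20, alpha = 0.05, seed = 5)
  thr2 <- permutation_threshold(cn, k = 20, alpha = 0.05, seed = 5)
  expect_identical(thr1, thr2)
  expect_error(permutation_threshold(cn, k = 5), "k >= 10")
  # equal node weights: permuting changes nothing, every normalized cost is
  # exactly 1, and the null distribution coincides with the observed one
  cn_eq <- condition_network(g, setNames(rep(1, 40), res$gene), "active")
  ranked_eq <- rank_paths(shortest_paths_all_pairs(cn_eq))
  thr_eq <- permutation_threshold(cn_eq, k = 10, alpha = 0.5, seed = 6)
  expect_equal(thr_eq, 1)
  expect_equal(unique(ranked_eq$normalized_cost), 1)
  # under exchangeable random weights (no planted signal) selection at
  # alpha retains roughly an alpha fraction of the observed paths
  null_res <- wald_test(small_counts(seed = 16, n_genes = 40)$counts,
                        "test", "ref")
  cn_null <- condition_network(g, setNames(2^null_res$log2fc, null_res$gene),
                               "active")
  ranked_null <- rank_paths(shortest_paths_all_pairs(cn_null))
  thr_null <- permutation_threshold(cn_null, k = 20, alpha = 0.1, seed = 7)
  frac <- mean(ranked_null$normalized_cost < thr_null)
  expect_lt(abs(frac - 0.1), 0.1)
  # a strongly upweighted planted module sits below a stringent threshold
  thr <- permutation_threshold(cn, k = 20, alpha = 0.01, seed = 8)
  sel <- select_top_paths(rank_paths(shortest_paths_all_pairs(cn)),
                          threshold = thr)
  mod_edges <- sel[vapply(strsplit(sel$path, "|", fixed = TRUE),
                          function(s) all(s %in% sprintf("g%04d", 1:8)),
                          logical(1)), ]
  expect_gt(nrow(mod_edges), 0)
})

test_that("TopNet assembly unions paths and intersects modes", {
  mk <- function(paths) {
    df <- data.frame(source = rep("x", length(paths)),
                     target = rep("y", length(paths)),
                     cost = rep(1, length(paths)),
                     n_edges = rep(1L, length(paths)),
                     normalized_cost = rep(1, length(paths)), path = paths)
    class(df) <- c("path_set", "data.frame")
    df
  }
  degs <- data.frame(gene = c("a", "b", "z"),
                     direction = c("up", "down", "up"))
  tn <- build_topnet(mk(c("a|b", "b|c")), mk("d|e"), degs)
  expect_identical(tn$active_nodes, c("a", "b", "c"))
  expect_identical(tn$repressed_nodes, c("d", "e"))
  expect_identical(tn$common_nodes, character(0))
  expect_identical(tn$captured_degs$gene, c("a", "b"))
  # identical path sets -> all nodes common
  tn2 <- build_topnet(mk("a|b"), mk("a|b"), degs)
  expect_identical(tn2$common_nodes, c("a", "b"))
  expect_warning(build_topnet(mk(character(0)), mk(character(0)), degs),
                 "empty")
})

test_that("mined TopNets capture a strongly planted module", {
  d <- demo_study(seed = 4)
  st <- d$study
  res <- wald_test(st$counts, "RHD", "ARF")
  tn <- mine_topnet(st$network, res)
  mod <- st$modules$module_RHD
  called <- deg_list(res)$gene
  expect_gte(mean(mod %in% called), 0.8)
  expect_gte(mean(intersect(mod, called) %in% tn$captured_degs$gene), 0.7)
  expect_identical(tn$provenance$comparison, "RHD_vs_ARF")
  # output tables are writable and consistent
  dir <- withr::local_tempdir()
  write_topnet(tn, dir)
  nodes <- read.delim(file.path(dir, "nodes.tsv"))
  edges <- read.delim(file.path(dir, "edges.tsv"))
  expect_setequal(nodes$node, union(tn$active_nodes, tn$repressed_nodes))
  expect_true(all(edges$source %in% nodes$node))
})
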