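# Independent oracles and small fixture builders used across test files.

# Exhaustive shortest-path oracle: enumerates every simple path from s to t
# by depth-first search and returns the minimum-cost path, ties broken by
# the lexicographically smallest node sequence. Deliberately independent of
# the Dijkstra-based implementation.
enumerate_shortest_path <- function(edges, s, t) {
  # edges: data.frame(source, target, weight)
  best <- list(cost = Inf, path = NULL)
  recurse <- function(node, visited, cost, path) {
    if (node == t) {
      if (cost < best$cost - 1e-12 ||
          (abs(cost - best$cost) <= 1e-12 &&
           paste(path, collapse = "\r") < paste(best$path, collapse = "\r"))) {
        best <<- list(cost = cost, path = path)
      }
      return(invisible())
    }
    out <- edges[edges$source == node & !(edges$target %in% visited), ,
                 drop = FALSE]
    for (i in seq_len(nrow(out))) {
      recurse(out$target[i], c(visited, out$target[i]),
              cost + out$weight[i], c(path, out$target[i]))
    }
  }
  recurse(s, s, 0, s)
  best
}

# seeded random directed weighted graph on single-letter node names
random_test_graph <- function(n, p = 0.35, seed = 1) {
  set.seed(seed)
  nodes <- letters[seq_len(n)]
  pairs <- expand.grid(source = nodes, target = nodes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  keep <- runif(nrow(pairs)) < p
  el <- pairs[keep, , drop = FALSE]
  el$weight <- round(runif(nrow(el), 0.05, 1), 3)
  el
}

# wrap an arbitrary weighted igraph as a condition_network so the path
# machinery can be tested on graphs with hand-set edge weights
as_cnet <- function(edges) {
  g <- igraph::graph_from_data_frame(edges[, c("source", "target")],
                                     directed = TRUE)
  igraph::E(g)$weight <- edges$weight
  structure(list(graph = g, mode = "active", dropped = character()),
            class = "condition_network")
}

# brute-force hypergeometric upper tail via log-binomials; independent of
# stats::phyper
brute_hyper_tail <- function(k, K, n, N) {
  i <- seq(max(k, 0, n + K - N), min(K, n))
  if (!length(i)) return(0)
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

# small two-group NB count matrix for DE tests
small_counts <- function(seed = 1, n_genes = 60, n_per_group = 5,
                         planted = NULL, dispersion = 0.1) {
  cfg <- simulation_config(n_genes = n_genes,
                           group_sizes = c(ref = n_per_group,
                                           test = n_per_group),
                           planted_effects = planted,
                           dispersion = dispersion,
                           network_nodes = 2, seed = seed)
  simulate_counts(cfg)
}
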