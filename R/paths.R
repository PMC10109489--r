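# All-pairs shortest perturbation paths and their ranking.
#
# Costs come from Dijkstra (igraph::distances); the path *sequences* are
# reconstructed here so that tie-breaking is well-defined: among equal-cost
# shortest paths the lexicographically smallest node sequence is returned,
# making outputs platform-independent.

#' All-pairs shortest paths of a condition network
#'
#' Runs Dijkstra between every ordered pair of nodes (positive edge weights
#' are required and guaranteed by construction) and reconstructs, for each
#' reachable pair, the minimum-cost path with the lexicographically
#' smallest node sequence. Each record carries the path cost (sum of edge
#' weights) and the normalized cost (cost divided by the number of edges),
#' which is the ranking criterion: a low normalized cost marks a path
#' running through highly perturbed genes.
#'
#' @param cnet a [condition_network()].
#' @return a data frame of class `path_set` with columns `source`,
#'   `target`, `cost`, `n_edges`, `normalized_cost`, `path` (node ids
#'   joined by `"|"`). Unreachable pairs are omitted.
#' @export
shortest_paths_all_pairs <- function(cnet) {
  stopifnot(inherits(cnet, "condition_network"))
  g <- cnet$graph
  n <- igraph::vcount(g)
  if (n == 0) stop("empty network")
  nm <- igraph::V(g)$name
  ew <- igraph::E(g)$weight
  D <- igraph::distances(g, mode = "out", weights = ew,
                         algorithm = "dijkstra")
  # adjacency sorted by node name (C collation, locale-independent), so the
  # first admissible successor is the lexicographically smallest
  sorted_nm <- sort(nm, method = "radix")
  rk <- match(nm, sorted_nm)
  el <- igraph::as_edgelist(g, names = FALSE)
  adj <- vector("list", n)
  wadj <- vector("list", n)
  for (u in seq_len(n)) adj[[u]] <- integer()
  if (nrow(el)) {
    o <- order(el[, 1], rk[el[, 2]])
    el <- el[o, , drop = FALSE]
    w <- ew[o]
    sp <- split(seq_len(nrow(el)), el[, 1])
    for (u in names(sp)) {
      idx <- sp[[u]]
      adj[[as.integer(u)]] <- el[idx, 2]
      wadj[[as.integer(u)]] <- w[idx]
    }
  }
  out <- vector("list", n)
  for (s in seq_len(n)) {
    Ds <- D[s, ]
    targets <- which(is.finite(Ds) & seq_len(n) != s)
    if (!length(targets)) next
    paths <- character(length(targets))
    hops <- integer(length(targets))
    for (ti in seq_along(targets)) {
      t <- targets[ti]
      tol <- 1e-9 * (1 + abs(Ds[t]))
      u <- s
      seqn <- integer(0)
      repeat {
        seqn <- c(seqn, u)
        if (u == t) break
        vs <- adj[[u]]
        keep <- Ds[u] + wadj[[u]] + D[vs, t] <= Ds[t] + tol
        u <- vs[which(keep)[1]]
      }
      hops[ti] <- length(seqn) - 1L
      paths[ti] <- paste(nm[seqn], collapse = "|")
    }
    out[[s]] <- data.frame(source = nm[s], target = nm[targets],
                           cost = Ds[targets], n_edges = hops,
                           normalized_cost = Ds[targets] / hops,
                           path = paths)
  }
  res <- do.call(rbind, out) %||%
    data.frame(source = character(), target = character(), cost = numeric(),
               n_edges = integer(), normalized_cost = numeric(),
               path = character())
  rownames(res) <- NULL
  attr(res, "nodes") <- sorted_nm
  class(res) <- c("path_set", "data.frame")
  res
}

# lexicographic sort key for a node sequence: fixed-width rank of each node
# within the sorted node universe
path_seq_key <- function(paths, nodes) {
  vapply(strsplit(paths, "|", fixed = TRUE), function(s)
    paste(sprintf("%06d", match(s, nodes)), collapse = ""), character(1))
}

#' Rank perturbation paths
#'
#' Ascending by normalized cost (most perturbed first); ties broken by raw
#' cost, then by the lexicographically smallest node sequence, so the order
#' is a pure function of the path set.
#'
#' @param paths a [shortest_paths_all_pairs()] result.
#' @return the same data frame, reordered, with a `rank` column prepended.
#' @export
rank_paths <- function(paths) {
  nodes <- attr(paths, "nodes") %||%
    sort(unique(c(paths$source, paths$target)), method = "radix")
  o <- order(paths$normalized_cost, paths$cost)
  p <- paths[o, , drop = FALSE]
  # resolve exact ties on (normalized_cost, cost) by node sequence
  key <- paste(sprintf("%.17g", p$normalized_cost),
               sprintf("%.17g", p$cost))
  dup <- key %in% key[duplicated(key)]
  if (any(dup)) {
    for (k in unique(key[dup])) {
      idx <- which(key == k)
      p[idx, ] <- p[idx[order(path_seq_key(p$path[idx], nodes))], ]
    }
  }
  p <- cbind(rank = seq_len(nrow(p)), p)
  rownames(p) <- NULL
  attr(p, "nodes") <- nodes
  class(p) <- c("path_set", "data.frame")
  p
}

#' Select the top perturbed paths
#'
#' Either the lowest-normalized-cost `ceiling(fraction * n)` paths, or (when
#' `threshold` is given, e.g. from [permutation_threshold()]) all paths with
#' normalized cost strictly below the threshold.
#'
#' @param ranked a [rank_paths()] result.
#' @param fraction fraction of paths to keep, in (0, 1].
#' @param threshold optional normalized-cost cutoff overriding `fraction`.
#' @return the selected subset, still a `path_set`.
#' @export
select_top_paths <- function(ranked, fraction = 0.005, threshold = NULL) {
  if (!is.null(threshold)) {
    keep <- ranked[ranked$normalized_cost < threshold, , drop = FALSE]
    if (!nrow(keep)) warning("threshold below the minimum path cost; no paths selected")
  } else {
    if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
    keep <- utils::head(ranked, ceiling(fraction * nrow(ranked)))
  }
  attr(keep, "nodes") <- attr(ranked, "nodes")
  class(keep) <- c("path_set", "data.frame")
  keep
}

#' Permutation null threshold for path selection
#'
#' Permutes the node weights across nodes `k` times; each permutation keeps
#' the graph topology and the weight multiset but destroys the association
#' between perturbation and position. Edge weights and all-pairs normalized
#' path costs are recomputed per permutation and pooled; the alpha-quantile
#' of this null distribution is returned as a principled selection cutoff.
#'
#' @param cnet a [condition_network()].
#' @param k number of permutations (at least 10).
#' @param alpha quantile level of the pooled null.
#' @param seed integer seed.
#' @return a single normalized-cost threshold.
#' @export
permutation_threshold <- function(cnet, k = 100, alpha = 0.01, seed = 1L) {
  stopifnot(inherits(cnet, "condition_network"), k >= 10)
  g <- cnet$graph
  n <- igraph::vcount(g)
  w0 <- igraph::V(g)$weight
  el <- igraph::as_edgelist(g, names = FALSE)
  vs <- igraph::V(g)
  with_seed(seed, {
    null_costs <- vector("list", k)
    for (i in seq_len(k)) {
      w <- sample(w0)
      ew <- compute_edge_weight(w[el[, 1]], w[el[, 2]])
      D <- igraph::distances(g, mode = "out", weights = ew,
                             algorithm = "dijkstra")
      hops <- matrix(NA_integer_, n, n)
      for (s in seq_len(n)) {
        sp <- suppressWarnings(
          igraph::shortest_paths(g, from = s, to = vs, mode = "out",
                                 weights = ew, output = "vpath"))
        hops[s, ] <- lengths(sp$vpath) - 1L
      }
      ok <- is.finite(D) & hops > 0
      null_costs[[i]] <- D[ok] / hops[ok]
    }
    stats::quantile(unlist(null_costs), probs = alpha, names = FALSE,
                    type = 7)
  })
}
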