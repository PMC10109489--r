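# TopNet assembly: the union of the top-ranked perturbation paths of the
# active and repressed condition networks for one comparison.

split_paths <- function(path_set) {
  lapply(strsplit(path_set$path, "|", fixed = TRUE), identity)
}

paths_nodes_edges <- function(path_set) {
  seqs <- strsplit(path_set$path, "|", fixed = TRUE)
  nodes <- sort(unique(unlist(seqs)) %||% character(), method = "radix")
  edges <- unique(do.call(rbind, lapply(seqs, function(s) {
    if (length(s) < 2) return(NULL)
    cbind(s[-length(s)], s[-1])
  })))
  if (is.null(edges) || !nrow(edges)) edges <- matrix(character(), 0, 2)
  else edges <- edges[order(edges[, 1], edges[, 2], method = "radix"), ,
                      drop = FALSE]
  list(nodes = nodes,
       edges = data.frame(source = edges[, 1], target = edges[, 2]))
}

#' Assemble a TopNet from selected active and repressed paths
#'
#' The active subnetwork is the union of nodes and edges of the selected
#' active-mode paths, likewise the repressed subnetwork; the common part is
#' their node intersection. Captured DEGs are the DEGs that fall inside the
#' combined node set.
#'
#' @param active_paths,repressed_paths selected [select_top_paths()] path
#'   sets from the same comparison.
#' @param degs data frame with columns `gene` and `direction` (e.g. from
#'   [deg_list()]).
#' @param provenance optional list recording comparison name and cutoff.
#' @return an object of class `topnet`: list with `active_nodes`,
#'   `active_edges`, `repressed_nodes`, `repressed_edges`, `common_nodes`,
#'   `captured_degs` (data frame), `active_paths`, `repressed_paths`,
#'   `provenance`.
#' @export
build_topnet <- function(active_paths, repressed_paths, degs,
                         provenance = list()) {
  if (!nrow(active_paths) && !nrow(repressed_paths))
    warning("no paths selected in either mode; TopNet is empty")
  act <- paths_nodes_edges(active_paths)
  rep_ <- paths_nodes_edges(repressed_paths)
  all_nodes <- union(act$nodes, rep_$nodes)
  captured <- degs[degs$gene %in% all_nodes, , drop = FALSE]
  rownames(captured) <- NULL
  structure(list(active_nodes = act$nodes, active_edges = act$edges,
                 repressed_nodes = rep_$nodes, repressed_edges = rep_$edges,
                 common_nodes = intersect(act$nodes, rep_$nodes),
                 captured_degs = captured,
                 active_paths = active_paths,
                 repressed_paths = repressed_paths,
                 provenance = provenance),
            class = "topnet")
}

#' @export
print.topnet <- function(x, ...) {
  nn <- length(union(x$active_nodes, x$repressed_nodes))
  ne <- nrow(unique(rbind(x$active_edges, x$repressed_edges)))
  cat(sprintf("topnet%s: %d nodes, %d edges\n",
              if (!is.null(x$provenance$comparison))
                paste0(" [", x$provenance$comparison, "]") else "", nn, ne))
  cat(sprintf("  active: %d nodes / %d edges; repressed: %d nodes / %d edges; common: %d nodes\n",
              length(x$active_nodes), nrow(x$active_edges),
              length(x$repressed_nodes), nrow(x$repressed_edges),
              length(x$common_nodes)))
  cat(sprintf("  captured DEGs: %d (%d up / %d down)\n",
              nrow(x$captured_degs),
              sum(x$captured_degs$direction == "up"),
              sum(x$captured_degs$direction == "down")))
  invisible(x)
}

#' Mine the TopNet of one comparison
#'
#' End-to-end network stage: converts a differential-expression result into
#' ratio-scale fold changes, builds the active and repressed condition
#' networks, runs all-pairs shortest-path mining in each, ranks paths by
#' normalized cost, selects the top paths (fixed fraction or permutation
#' threshold) and assembles the TopNet.
#'
#' @param network an igraph interaction network with named vertices.
#' @param deg_result a [wald_test()] result for the comparison.
#' @param fraction fraction of top-ranked paths kept per mode.
#' @param use_permutation select by [permutation_threshold()] instead of a
#'   fixed fraction.
#' @param k,alpha,seed permutation-threshold parameters.
#' @param undirected symmetrize the network before mining.
#' @return a [build_topnet()] object with provenance.
#' @export
mine_topnet <- function(network, deg_result, fraction = 0.005,
                        use_permutation = FALSE, k = 100, alpha = 0.01,
                        seed = 1L, undirected = FALSE) {
  stopifnot(inherits(deg_result, "deg_result"))
  if (undirected)
    network <- igraph::as.undirected(network, mode = "collapse")
  fc <- stats::setNames(2^deg_result$log2fc, deg_result$gene)
  one_mode <- function(mode) {
    cn <- condition_network(network, fc, mode)
    ranked <- rank_paths(shortest_paths_all_pairs(cn))
    thr <- if (use_permutation)
      permutation_threshold(cn, k = k, alpha = alpha, seed = seed)
    else NULL
    list(net = cn,
         sel = select_top_paths(ranked, fraction = fraction, threshold = thr),
         threshold = thr)
  }
  act <- one_mode("active")
  rep_ <- one_mode("repressed")
  cmp <- attr(deg_result, "comparison")
  prov <- list(comparison = if (!is.null(cmp))
                 paste0(cmp[["test"]], "_vs_", cmp[["reference"]]) else NA,
               selection = if (use_permutation) "permutation" else "fraction",
               fraction = if (use_permutation) NA else fraction,
               threshold_active = act$threshold %||% NA,
               threshold_repressed = rep_$threshold %||% NA,
               dropped_nodes = length(act$net$dropped))
  tn <- build_topnet(act$sel, rep_$sel, deg_list(deg_result),
                     provenance = prov)
  tn$node_weights <- list(
    active = stats::setNames(igraph::V(act$net$graph)$weight,
                             igraph::V(act$net$graph)$name),
    repressed = stats::setNames(igraph::V(rep_$net$graph)$weight,
                                igraph::V(rep_$net$graph)$name))
  tn
}

#' Write a TopNet as Cytoscape-importable tables
#'
#' Writes `nodes.tsv` (node, weight in its mode's network, mode in
#' active/repressed/common, DEG flag and direction), `edges.tsv` (source,
#' target, mode, edge weight) and `paths.tsv` (rank, mode, normalized cost,
#' node sequence joined by `"|"`).
#'
#' @param topnet a [mine_topnet()] result.
#' @param dir output directory (created if missing).
#' @return invisibly, the directory.
#' @export
write_topnet <- function(topnet, dir) {
  stopifnot(inherits(topnet, "topnet"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nodes <- union(topnet$active_nodes, topnet$repressed_nodes)
  nodes <- sort(nodes, method = "radix")
  mode <- ifelse(nodes %in% topnet$common_nodes, "common",
                 ifelse(nodes %in% topnet$active_nodes, "active",
                        "repressed"))
  wact <- topnet$node_weights$active %||% numeric()
  wrep <- topnet$node_weights$repressed %||% numeric()
  weight <- ifelse(mode == "repressed", wrep[nodes], wact[nodes])
  cap <- topnet$captured_degs
  ndf <- data.frame(node = nodes, weight = weight, mode = mode,
                    is_deg = nodes %in% cap$gene,
                    direction = ifelse(nodes %in% cap$gene,
                                       cap$direction[match(nodes, cap$gene)],
                                       "none"))
  write_tsv(ndf, file.path(dir, "nodes.tsv"))
  ew <- function(df, mode, w) {
    if (!nrow(df)) return(cbind(df[0, ], mode = character(), weight = numeric()))
    data.frame(df, mode = mode,
               weight = compute_edge_weight(w[df$source], w[df$target]))
  }
  edf <- rbind(ew(topnet$active_edges, "active", wact),
               ew(topnet$repressed_edges, "repressed", wrep))
  write_tsv(edf, file.path(dir, "edges.tsv"))
  pth <- function(ps, mode)
    if (nrow(ps)) data.frame(rank = ps$rank, mode = mode,
                             normalized_cost = ps$normalized_cost,
                             path = ps$path)
    else data.frame(rank = integer(), mode = character(),
                    normalized_cost = numeric(), path = character())
  write_tsv(rbind(pth(topnet$active_paths, "active"),
                  pth(topnet$repressed_paths, "repressed")),
            file.path(dir, "paths.tsv"))
  invisible(dir)
}
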