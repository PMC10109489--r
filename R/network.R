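# Interaction networks and condition-specific weighting.
#
# Node weights carry per-gene perturbation (fold change in "active" mode,
# its reciprocal in "repressed" mode); each edge gets weight
# 1/sqrt(product of its endpoint node weights), so edges between highly
# perturbed genes are cheap and shortest paths preferentially run through
# the most perturbed part of the network.

#' Read a network from a SIF file
#'
#' Simple interaction format: one edge per line,
#' `source<TAB>interaction<TAB>target` (a 2-column `source<TAB>target`
#' edge list is also accepted). Self-loops are dropped with a message.
#'
#' @param path file path.
#' @param directed treat edges as directed (default) or symmetrize.
#' @return a named igraph graph.
#' @export
read_sif <- function(path, directed = TRUE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  el <- t(vapply(parts, function(f) {
    if (length(f) >= 3) c(f[1], f[3]) else if (length(f) == 2) c(f[1], f[2])
    else stop("malformed SIF line: ", paste(f, collapse = "\t"))
  }, character(2)))
  loops <- el[, 1] == el[, 2]
  if (any(loops)) {
    message("dropping ", sum(loops), " self-loop(s)")
    el <- el[!loops, , drop = FALSE]
  }
  g <- igraph::graph_from_edgelist(el, directed = directed)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Write a network to a SIF file
#'
#' @param network an igraph graph with named vertices.
#' @param path output path.
#' @param interaction interaction type written in the middle column.
#' @return invisibly, `path`.
#' @export
write_sif <- function(network, path, interaction = "pp") {
  el <- igraph::as_edgelist(network)
  writeLines(sprintf("%s\t%s\t%s", el[, 1], interaction, el[, 2]), path)
  invisible(path)
}

#' Condition-specific node weights from fold changes
#'
#' Active mode uses the test/reference fold change directly, so upregulated
#' genes weigh high; repressed mode uses its reciprocal (equivalently the
#' reference/test ratio), so downregulated genes weigh high. Swapping test
#' and reference therefore maps the active network onto the repressed one.
#'
#' @param fold_changes named numeric vector of strictly positive
#'   ratio-scale fold changes (test over reference).
#' @param mode `"active"` or `"repressed"`.
#' @return named numeric vector of positive node weights.
#' @export
compute_node_weights <- function(fold_changes, mode = c("active", "repressed")) {
  mode <- match.arg(mode)
  bad <- !is.finite(fold_changes) | fold_changes <= 0
  if (any(bad))
    stop("non-positive fold change for gene(s): ",
         paste(names(fold_changes)[bad], collapse = ", "))
  if (mode == "active") fold_changes else 1 / fold_changes
}

#' Edge weight from its endpoint node weights
#'
#' @param w_u,w_v positive node weights.
#' @return `1 / sqrt(w_u * w_v)`; symmetric in its arguments.
#' @export
compute_edge_weight <- function(w_u, w_v) {
  if (any(w_u <= 0) || any(w_v <= 0)) stop("node weights must be positive")
  1 / sqrt(w_u * w_v)
}

#' Build a condition-specific weighted network
#'
#' Drops network nodes without a fold change (their perturbation is
#' unknown; imputing a weight would fabricate signal), attaches node
#' weights per `mode`, and derives every edge weight as
#' `1/sqrt(w_u * w_v)`.
#'
#' @param network an igraph graph with named vertices.
#' @param fold_changes named positive fold-change vector (ratio scale).
#' @param mode `"active"` or `"repressed"`.
#' @return an object of class `condition_network`: list with `graph` (the
#'   weighted igraph subgraph, vertex attribute `weight`, edge attribute
#'   `weight`), `mode`, and `dropped` (nodes removed for lack of a fold
#'   change).
#' @export
condition_network <- function(network, fold_changes,
                              mode = c("active", "repressed")) {
  mode <- match.arg(mode)
  nodes <- igraph::V(network)$name
  dropped <- setdiff(nodes, names(fold_changes))
  if (length(dropped))
    message(length(dropped), " network node(s) without expression dropped")
  g <- igraph::induced_subgraph(network, setdiff(nodes, dropped))
  w <- compute_node_weights(fold_changes[igraph::V(g)$name], mode)
  igraph::V(g)$weight <- unname(w)
  el <- igraph::as_edgelist(g, names = FALSE)
  igraph::E(g)$weight <- compute_edge_weight(igraph::V(g)$weight[el[, 1]],
                                             igraph::V(g)$weight[el[, 2]])
  structure(list(graph = g, mode = mode, dropped = dropped),
            class = "condition_network")
}

#' @export
print.condition_network <- function(x, ...) {
  cat(sprintf("condition_network (%s): %d nodes, %d edges", x$mode,
              igraph::vcount(x$graph), igraph::ecount(x$graph)))
  if (length(x$dropped)) cat(sprintf(", %d dropped", length(x$dropped)))
  cat("\n")
  invisible(x)
}
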