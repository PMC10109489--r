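# Gene-set over-representation testing (one-sided Fisher's exact /
# hypergeometric upper tail), GMT I/O.

# P(X >= k) for X ~ Hypergeom(N, K, n): the one-sided Fisher p-value of the
# 2x2 table (in query / not) x (in set / not)
hyper_tail_p <- function(k, K, n, N) {
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors (term -> member genes); every
#'   set must be non-empty.
#' @param universe background gene ids. Set members outside the universe are
#'   dropped with a message (id harmonization).
#' @return an object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, universe) {
  stopifnot(is.list(sets))
  if (length(sets) && is.null(names(sets))) stop("sets must be named")
  if (any(!lengths(sets))) stop("every gene set must be non-empty")
  universe <- unique(as.character(universe))
  harmonized <- lapply(sets, function(s) intersect(unique(s), universe))
  dropped <- sum(lengths(sets) - lengths(harmonized))
  if (dropped > 0)
    message(dropped, " gene-set member(s) outside the universe dropped")
  harmonized <- harmonized[lengths(harmonized) > 0]
  structure(list(sets = harmonized, universe = universe),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets over %d universe genes\n",
              length(x$sets), length(x$universe)))
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: `name<TAB>description<TAB>gene1<TAB>gene2...`, one set per
#' line. An empty file yields an empty collection.
#'
#' @param path file path.
#' @param universe background genes; defaults to the union of all set
#'   members.
#' @return a [gene_set_collection()]; descriptions kept as an attribute.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[`, character(1), 1)
  desc <- vapply(fields, `[`, character(1), 2)
  col <- gene_set_collection(sets,
                             universe %||% unique(unlist(sets)) %||% character())
  attr(col, "descriptions") <- stats::setNames(desc, names(sets))
  col
}

#' Write gene sets to a GMT file
#'
#' @param collection a [gene_set_collection()] (or named list of sets).
#' @param path output path.
#' @param descriptions optional named character vector of descriptions;
#'   defaults to `"na"`.
#' @return invisibly, `path`.
#' @export
write_gmt <- function(collection, path, descriptions = NULL) {
  sets <- if (inherits(collection, "gene_set_collection")) collection$sets
          else collection
  descriptions <- descriptions %||% attr(collection, "descriptions")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(descriptions) && nm %in% names(descriptions))
      descriptions[[nm]] else "na"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' One-sided Fisher over-representation test of a query gene set
#'
#' For each term, tests over-representation of the query in the set with the
#' hypergeometric upper tail of the 2x2 table (in query / not) x (in set /
#' not) over the collection's universe: `p = P(X >= k)` with
#' `X ~ Hypergeom(N, K, n)`. Query genes outside the universe are dropped
#' with a message. Results are sorted ascending by p with BH-adjusted
#' p-values.
#'
#' @param query character vector of gene ids.
#' @param collection a [gene_set_collection()].
#' @return data frame of class `enrichment_result` with columns `term`,
#'   `k` (overlap), `K` (set size), `n` (query size), `N` (universe size),
#'   `p`, `p_bh`, `genes` (overlap members joined by `";"`).
#' @export
fisher_enrichment <- function(query, collection) {
  stopifnot(inherits(collection, "gene_set_collection"))
  query <- unique(as.character(query))
  outside <- setdiff(query, collection$universe)
  if (length(outside)) {
    message(length(outside), " query gene(s) outside the universe dropped")
    query <- setdiff(query, outside)
  }
  if (!length(query)) {
    warning("empty query; no enrichment computed")
    out <- data.frame(term = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      p_bh = numeric(), genes = character())
    class(out) <- c("enrichment_result", "data.frame")
    return(out)
  }
  N <- length(collection$universe)
  n <- length(query)
  rows <- lapply(names(collection$sets), function(term) {
    set <- collection$sets[[term]]
    ov <- intersect(query, set)
    k <- length(ov)
    K <- length(set)
    p <- hyper_tail_p(k, K, n, N)
    data.frame(term = term, k = k, K = K, n = n, N = N, p = p,
               genes = paste(sort(ov, method = "radix"), collapse = ";"))
  })
  out <- do.call(rbind, rows)
  out$p_bh <- adjust_pvalues(out$p, "BH")
  out <- out[order(out$p, out$term, method = "radix"),
             c("term", "k", "K", "n", "N", "p", "p_bh", "genes")]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Filter enrichment results by significance
#'
#' Retains terms with p (or BH-adjusted p) strictly below `alpha`,
#' preserving order.
#'
#' @param results a [fisher_enrichment()] result.
#' @param alpha significance level (strict).
#' @param use_adjusted filter on `p_bh` instead of raw `p`.
#' @return the retained subset.
#' @export
filter_significant <- function(results, alpha = 0.05, use_adjusted = FALSE) {
  pv <- if (use_adjusted) results$p_bh else results$p
  out <- results[pv < alpha, , drop = FALSE]
  rownames(out) <- NULL
  out
}
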