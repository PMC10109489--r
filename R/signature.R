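# Cross-comparison exclusion signature and sample clustering.

#' Define a study design
#'
#' Names a set of pairwise comparisons, the primary comparison whose
#' captured DEGs form the candidate signature, and the control comparisons
#' whose captured DEGs are excluded from it.
#'
#' @param comparisons data frame with columns `name`, `test`, `reference`.
#' @param primary name of the primary comparison.
#' @param controls character vector of control comparison names.
#' @return an object of class `study_design`.
#' @export
study_design <- function(comparisons, primary, controls) {
  comparisons <- as.data.frame(comparisons)
  stopifnot(all(c("name", "test", "reference") %in% names(comparisons)))
  if (anyDuplicated(comparisons$name)) stop("comparison names must be unique")
  if (!primary %in% comparisons$name) stop("unknown primary comparison")
  if (!all(controls %in% comparisons$name)) stop("unknown control comparison")
  if (primary %in% controls) stop("primary comparison cannot be a control")
  structure(list(comparisons = comparisons, primary = primary,
                 controls = controls), class = "study_design")
}

#' The four-comparison rheumatic heart disease design
#'
#' Primary comparison RHD vs ARF; controls RHD vs HC, ARF vs HC and
#' CHD vs HC, whose captured DEGs are excluded to leave genes
#' characteristic of the disease-versus-precursor contrast.
#'
#' @return a [study_design()].
#' @export
rhd_study_design <- function() {
  study_design(
    data.frame(name = c("RHD_vs_ARF", "RHD_vs_HC", "ARF_vs_HC", "CHD_vs_HC"),
               test = c("RHD", "RHD", "ARF", "CHD"),
               reference = c("ARF", "HC", "HC", "HC")),
    primary = "RHD_vs_ARF",
    controls = c("RHD_vs_HC", "ARF_vs_HC", "CHD_vs_HC"))
}

#' Condition-characteristic signature by cross-comparison exclusion
#'
#' Subtracts, from the primary comparison's captured DEGs, every gene
#' captured by any control comparison's TopNet. Exclusion is by gene
#' identity (directions are kept for reporting but ignored when matching).
#' Provenance records the set size after each subtraction.
#'
#' @param primary_captured data frame `gene`, `direction` (and optionally
#'   more columns) of DEGs captured by the primary TopNet.
#' @param control_captured list of data frames (or character vectors) of
#'   genes captured by each control TopNet; list names label the
#'   provenance steps.
#' @return an object of class `signature_set`: list with `genes` (data
#'   frame, the retained rows of `primary_captured`) and `provenance`
#'   (initial size and size after each subtraction).
#' @export
characteristic_degs <- function(primary_captured, control_captured = list()) {
  if (is.character(primary_captured))
    primary_captured <- data.frame(gene = primary_captured,
                                   direction = "none")
  keep <- primary_captured
  steps <- list(initial = nrow(keep))
  nms <- names(control_captured) %||%
    sprintf("control_%d", seq_along(control_captured))
  if (length(control_captured) && is.null(names(control_captured)))
    names(control_captured) <- nms
  for (nm in names(control_captured)) {
    ctrl <- control_captured[[nm]]
    genes <- if (is.data.frame(ctrl)) ctrl$gene else as.character(ctrl)
    keep <- keep[!keep$gene %in% genes, , drop = FALSE]
    steps[[paste0("after_", nm)]] <- nrow(keep)
  }
  rownames(keep) <- NULL
  structure(list(genes = keep, provenance = steps), class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("signature_set: %d genes (%d up / %d down)\n",
              nrow(x$genes), sum(x$genes$direction == "up"),
              sum(x$genes$direction == "down")))
  sz <- unlist(x$provenance)
  cat("  ", paste(sprintf("%s=%d", names(sz), sz), collapse = " -> "), "\n")
  invisible(x)
}

#' Direction-concordant intersection of two DEG sets
#'
#' Genes present in both sets with the same direction; the result is
#' partitioned into up/up and down/down counts.
#'
#' @param deg_set_a,deg_set_b data frames with columns `gene`, `direction`.
#' @return data frame `gene`, `direction` with attribute `counts`
#'   (named vector `up`, `down`).
#' @export
common_degs <- function(deg_set_a, deg_set_b) {
  m <- merge(deg_set_a[, c("gene", "direction")],
             deg_set_b[, c("gene", "direction")], by = "gene")
  m <- m[m$direction.x == m$direction.y, , drop = FALSE]
  out <- data.frame(gene = m$gene, direction = m$direction.x)
  out <- out[order(out$gene, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "counts") <- c(up = sum(out$direction == "up"),
                           down = sum(out$direction == "down"))
  out
}

#' Hierarchically cluster samples on a gene list
#'
#' Restricts the normalized matrix to `gene_list`, scales each row (gene)
#' to mean 0 and sd 1 across samples (row Z-scores), drops constant rows
#' with a warning, and clusters the samples agglomeratively (Euclidean
#' distance, average linkage by default). The linkage contains no
#' randomness, so the leaf order is a pure function of the matrix.
#'
#' @param norm_counts numeric matrix, genes x samples (normalized counts).
#' @param gene_list genes to cluster on; must exist in the matrix.
#' @param distance a [stats::dist()] method.
#' @param linkage an [stats::hclust()] agglomeration method.
#' @return an object of class `sample_clustering`: list with `z`
#'   (row-scaled matrix), `hclust`, and `order` (leaf-order sample ids).
#' @export
cluster_samples <- function(norm_counts, gene_list, distance = "euclidean",
                            linkage = "average") {
  if (ncol(norm_counts) < 2) stop("clustering needs at least 2 samples")
  missing <- setdiff(gene_list, rownames(norm_counts))
  if (length(missing))
    stop("genes absent from matrix: ", paste(missing, collapse = ", "))
  m <- norm_counts[gene_list, , drop = FALSE]
  sds <- apply(m, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant row(s) dropped before scaling")
    m <- m[sds > 0, , drop = FALSE]
  }
  if (!nrow(m)) stop("no non-constant genes to cluster on")
  z <- t(scale(t(m)))
  hc <- stats::hclust(stats::dist(t(z), method = distance), method = linkage)
  structure(list(z = z, hclust = hc, order = colnames(z)[hc$order]),
            class = "sample_clustering")
}

#' @export
print.sample_clustering <- function(x, ...) {
  cat(sprintf("sample_clustering: %d genes x %d samples\n",
              nrow(x$z), ncol(x$z)))
  cat("  leaf order:", paste(x$order, collapse = " "), "\n")
  invisible(x)
}

#' @export
plot.sample_clustering <- function(x, ...) {
  stats::heatmap(x$z, Colv = stats::as.dendrogram(x$hclust), Rowv = NA,
                 scale = "none", ...)
  invisible(x)
}
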