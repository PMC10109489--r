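#' Construct a grouped count matrix
#'
#' Bundles an integer gene-by-sample count matrix with the group label of
#' each sample. This is the raw material of every pairwise comparison in the
#' pipeline.
#'
#' @param counts integer matrix, genes in rows, samples in columns; both
#'   dimensions must be named with unique ids.
#' @param groups character vector of group names, either named by sample id
#'   or in column order of `counts`.
#' @return an object of class `count_matrix`: a list with elements `counts`
#'   (integer matrix) and `groups` (named character vector, one entry per
#'   sample).
#' @examples
#' m <- matrix(rpois(12, 10), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' cm <- count_matrix(m, c(s1 = "A", s2 = "A", s3 = "B", s4 = "B"))
#' @export
count_matrix <- function(counts, groups) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene ids in counts")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids in counts")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != round(counts))) stop("counts must be integers")
  storage.mode(counts) <- "double"   # holds integer values; avoids overflow
  groups <- as.character(groups) |> stats::setNames(names(groups))
  if (is.null(names(groups))) {
    if (length(groups) != ncol(counts))
      stop("groups must have one entry per sample")
    names(groups) <- colnames(counts)
  }
  missing <- setdiff(colnames(counts), names(groups))
  if (length(missing))
    stop("samples without a group label: ", paste(missing, collapse = ", "))
  groups <- groups[colnames(counts)]
  structure(list(counts = counts, groups = groups), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  tab <- table(x$groups)
  cat(sprintf("count_matrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("groups:", paste(sprintf("%s (n=%d)", names(tab), tab),
                       collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Subset a count matrix to two comparison groups
#'
#' @param cm a [count_matrix()].
#' @param groups character vector of group names to keep.
#' @return a `count_matrix` containing only samples from `groups`.
#' @export
subset_groups <- function(cm, groups) {
  stopifnot(inherits(cm, "count_matrix"))
  unknown <- setdiff(groups, unique(cm$groups))
  if (length(unknown))
    stop("unknown group(s): ", paste(unknown, collapse = ", "))
  keep <- names(cm$groups)[cm$groups %in% groups]
  count_matrix(cm$counts[, keep, drop = FALSE], cm$groups[keep])
}

#' Read a count matrix and sample metadata from TSV files
#'
#' `counts.tsv` has gene ids in the first column and one integer column per
#' sample; `samples.tsv` has columns `sample_id` and `group`.
#'
#' @param counts_path path to the counts TSV.
#' @param samples_path path to the sample-metadata TSV.
#' @return a [count_matrix()].
#' @export
read_counts <- function(counts_path, samples_path) {
  df <- read_tsv(counts_path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  meta <- read_tsv(samples_path)
  if (!all(c("sample_id", "group") %in% names(meta)))
    stop("samples table needs columns sample_id and group")
  count_matrix(m, stats::setNames(meta$group, meta$sample_id))
}

#' Write a count matrix and sample metadata to TSV files
#'
#' @param cm a [count_matrix()].
#' @param counts_path,samples_path output file paths.
#' @return invisibly, the two paths.
#' @export
write_counts <- function(cm, counts_path, samples_path) {
  stopifnot(inherits(cm, "count_matrix"))
  df <- data.frame(gene = rownames(cm$counts), cm$counts,
                   check.names = FALSE)
  write_tsv(df, counts_path)
  write_tsv(data.frame(sample_id = names(cm$groups),
                       group = unname(cm$groups)), samples_path)
  invisible(c(counts_path, samples_path))
}
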