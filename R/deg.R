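# Differential expression: median-of-ratios normalization, moment
# dispersion, negative-binomial Wald test, DEG calling.

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over genes (restricted to
#' genes with a positive geometric mean across samples) of the ratio of the
#' sample's count to the gene's geometric mean; factors are rescaled to
#' geometric mean 1. When no gene is expressed in every sample the function
#' falls back to total-count ratios with a message.
#'
#' @param cm a [count_matrix()] or a bare counts matrix.
#' @return named positive numeric vector, one factor per sample.
#' @export
estimate_size_factors <- function(cm) {
  m <- if (inherits(cm, "count_matrix")) cm$counts else as.matrix(cm)
  logm <- log(m)
  gm <- rowMeans(logm)            # -Inf for any gene with a zero
  use <- is.finite(gm)
  if (!any(use)) {
    message("no gene expressed in all samples; using total-count ratios")
    sf <- colSums(m)
    sf <- sf / exp(mean(log(sf)))
    return(sf)
  }
  lr <- logm[use, , drop = FALSE] - gm[use]
  sf <- exp(apply(lr, 2, stats::median))
  sf / exp(mean(log(sf)))
}

#' Pooled method-of-moments dispersion
#'
#' Per gene, pools the within-group sample variance (df-weighted across
#' groups with at least two samples) and the mean of the normalized counts,
#' and solves `Var = mu + alpha * mu^2` for `alpha`, floored at `floor`.
#' Genes with zero mean (all-zero counts) sit at the floor.
#'
#' @param norm_counts matrix of normalized counts (genes x samples).
#' @param groups character vector of group labels, one per column.
#' @param floor lower bound for the dispersion estimate.
#' @return named numeric vector of per-gene dispersions `alpha >= floor`.
#' @export
estimate_dispersion <- function(norm_counts, groups, floor = 1e-8) {
  groups <- as.character(groups)
  tab <- table(groups)
  if (!any(tab >= 2))
    stop("dispersion estimation needs at least one group with >= 2 samples")
  use_groups <- names(tab)[tab >= 2]
  v <- 0; df <- 0
  for (g in use_groups) {
    sub <- norm_counts[, groups == g, drop = FALSE]
    v <- v + apply(sub, 1, stats::var) * (ncol(sub) - 1)
    df <- df + ncol(sub) - 1
  }
  s2 <- v / df
  mu <- rowMeans(norm_counts[, groups %in% use_groups, drop = FALSE])
  alpha <- ifelse(mu > 0, (s2 - mu) / mu^2, floor)
  pmax(alpha, floor)
}

#' Negative-binomial Wald test between two groups
#'
#' For each gene, the log2 fold change is
#' `log2((m_test + c) / (m_ref + c))` where `m` are means of
#' size-factor-normalized counts and `c` is a pseudocount keeping the ratio
#' finite for all-zero groups. The standard error comes from the delta
#' method applied to each group mean under `Var = mu + alpha * mu^2`; the
#' Wald statistic `log2fc / SE` is referred to a standard normal,
#' two-sided. Samples are subset to the two compared groups before
#' normalization and dispersion pooling.
#'
#' @param cm a [count_matrix()].
#' @param test_group,reference_group group names to compare (fold changes
#'   are test over reference).
#' @param pseudocount pseudocount `c` on normalized group means.
#' @param dispersion optional per-gene dispersion overriding the pooled
#'   moment estimate.
#' @param fold_threshold,alpha,use_adjusted DEG-calling thresholds passed to
#'   [call_degs()].
#' @return a data frame of class `deg_result` with columns `gene`,
#'   `base_mean`, `log2fc`, `se`, `wald_stat`, `p`, `p_bh`, `p_bonf`,
#'   `is_deg`, `direction`. Attributes record the comparison and a
#'   `low_confidence` flag when a group has a single sample.
#' @export
wald_test <- function(cm, test_group, reference_group, pseudocount = 0.5,
                      dispersion = NULL, fold_threshold = 2, alpha = 0.05,
                      use_adjusted = FALSE) {
  stopifnot(inherits(cm, "count_matrix"))
  if (test_group == reference_group)
    stop("test and reference groups must differ")
  two <- subset_groups(cm, c(test_group, reference_group))
  sf <- estimate_size_factors(two)
  norm <- sweep(two$counts, 2, sf, `/`)
  grp <- two$groups
  if (is.null(dispersion))
    dispersion <- estimate_dispersion(norm, grp)
  dispersion <- rep_len(dispersion, nrow(norm))

  group_stats <- function(g) {
    sub <- norm[, grp == g, drop = FALSE]
    n <- ncol(sub)
    mu <- rowMeans(sub)
    list(n = n, mu = mu, var_mean = (mu + dispersion * mu^2) / n)
  }
  ts <- group_stats(test_group)
  rs <- group_stats(reference_group)

  log2fc <- log2((ts$mu + pseudocount) / (rs$mu + pseudocount))
  # delta method: Var(log2 (m + c)) = Var(m) / ((m + c) ln 2)^2
  var_lfc <- (ts$var_mean / (ts$mu + pseudocount)^2 +
                rs$var_mean / (rs$mu + pseudocount)^2) / log(2)^2
  se <- sqrt(var_lfc)
  wald <- ifelse(se > 0, log2fc / se, 0)
  p <- ifelse(se > 0, 2 * stats::pnorm(-abs(wald)), 1)

  res <- data.frame(gene = rownames(norm),
                    base_mean = rowMeans(norm),
                    log2fc = log2fc, se = se, wald_stat = wald, p = p,
                    p_bh = adjust_pvalues(p, "BH"),
                    p_bonf = adjust_pvalues(p, "bonferroni"),
                    row.names = NULL)
  res <- call_degs(res, fold_threshold = fold_threshold, alpha = alpha,
                   use_adjusted = use_adjusted)
  attr(res, "comparison") <- c(test = test_group, reference = reference_group)
  attr(res, "n") <- c(test = ts$n, reference = rs$n)
  attr(res, "low_confidence") <- min(ts$n, rs$n) < 2
  class(res) <- c("deg_result", "data.frame")
  res
}

#' @export
print.deg_result <- function(x, ...) {
  cmp <- attr(x, "comparison")
  cat(sprintf("deg_result: %s vs %s (%d genes, %d DEGs: %d up / %d down)\n",
              cmp[["test"]], cmp[["reference"]], nrow(x), sum(x$is_deg),
              sum(x$direction == "up"), sum(x$direction == "down")))
  if (isTRUE(attr(x, "low_confidence")))
    cat("  note: a group has a single sample; results are low-confidence\n")
  print.data.frame(utils::head(as.data.frame(x)[order(x$p), ], 10))
  invisible(x)
}

#' Adjust p-values for multiple testing
#'
#' Thin wrapper over [stats::p.adjust()] exposing the two corrections the
#' pipeline uses: Benjamini-Hochberg step-up and Bonferroni.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param method `"BH"` or `"bonferroni"`.
#' @return adjusted p-values, same length and order as `p`.
#' @export
adjust_pvalues <- function(p, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (!length(p)) return(numeric())
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = method)
}

#' Call differentially expressed genes
#'
#' A gene is a DEG iff `|log2fc| >= log2(fold_threshold)` (inclusive) and
#' its p-value (raw, or Bonferroni-adjusted when `use_adjusted`) is strictly
#' below `alpha`. Direction is `up`/`down` by the sign of `log2fc`, `none`
#' for non-DEGs.
#'
#' @param results data frame with columns `log2fc`, `p` and (if
#'   `use_adjusted`) `p_bonf`.
#' @param fold_threshold fold-change threshold on the ratio scale.
#' @param alpha significance level (strict).
#' @param use_adjusted use the Bonferroni-adjusted p-value.
#' @return `results` with columns `is_deg` and `direction` set.
#' @export
call_degs <- function(results, fold_threshold = 2, alpha = 0.05,
                      use_adjusted = FALSE) {
  pv <- if (use_adjusted) results$p_bonf else results$p
  is_deg <- abs(results$log2fc) >= log2(fold_threshold) & pv < alpha
  results$is_deg <- is_deg
  results$direction <- ifelse(!is_deg, "none",
                              ifelse(results$log2fc > 0, "up", "down"))
  results
}

#' Extract the DEG list from a test result
#'
#' @param results a [wald_test()] result.
#' @return data frame `gene`, `direction`, `log2fc`, `p` for called DEGs.
#' @export
deg_list <- function(results) {
  out <- results[results$is_deg, c("gene", "direction", "log2fc", "p")]
  rownames(out) <- NULL
  as.data.frame(out)
}
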