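# Clinical blood-count statistics: neutrophil-to-lymphocyte ratio, group
# summaries (mean +/- SD), pairwise group comparisons.

#' Neutrophil-to-lymphocyte ratio
#'
#' `NLR = neutrophil / lymphocyte`. The two arguments may be percentages or
#' absolute counts; the ratio is identical as long as both share the same
#' denominator.
#'
#' @param neutrophil_pct,lymphocyte_pct numeric vectors; lymphocyte values
#'   must be strictly positive.
#' @return numeric vector of ratios.
#' @export
compute_nlr <- function(neutrophil_pct, lymphocyte_pct) {
  if (any(lymphocyte_pct <= 0, na.rm = TRUE))
    stop("lymphocyte percentage must be positive")
  neutrophil_pct / lymphocyte_pct
}

#' Per-group mean and SD of clinical parameters
#'
#' Summarizes every numeric column per group as sample mean and sample SD
#' (n - 1 denominator), excluding missing values pairwise; an NLR column is
#' derived per patient first (mean of per-patient ratios, so the summary
#' carries an SD). Groups with a single non-missing value report `NA` for
#' the SD.
#'
#' @param clinical data frame with a `group` column, `neutrophil_pct`,
#'   `lymphocyte_pct` and any further numeric parameter columns.
#' @return data frame with columns `group`, `parameter`, `n`, `mean`, `sd`.
#' @export
summarize_groups <- function(clinical) {
  stopifnot("group" %in% names(clinical))
  df <- clinical
  if (all(c("neutrophil_pct", "lymphocyte_pct") %in% names(df)) &&
      !"nlr" %in% names(df)) {
    ok <- !is.na(df$lymphocyte_pct) & df$lymphocyte_pct > 0
    df$nlr <- NA_real_
    df$nlr[ok] <- compute_nlr(df$neutrophil_pct[ok], df$lymphocyte_pct[ok])
  }
  params <- names(df)[vapply(df, is.numeric, logical(1))]
  rows <- list()
  for (g in unique(df$group)) {
    sub <- df[df$group == g, , drop = FALSE]
    for (p in params) {
      v <- sub[[p]][!is.na(sub[[p]])]
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, parameter = p, n = length(v),
        mean = if (length(v)) mean(v) else NA_real_,
        sd = if (length(v) >= 2) stats::sd(v) else NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Two-sample comparison of a clinical parameter
#'
#' Welch's t-test (default) or the Mann-Whitney U test (normal
#' approximation with mid-rank ties), two-sided.
#'
#' @param values_a,values_b numeric vectors.
#' @param test `"welch_t"` or `"mann_whitney"`.
#' @return list with `test`, `statistic`, `p`.
#' @export
compare_groups <- function(values_a, values_b,
                           test = c("welch_t", "mann_whitney")) {
  test <- match.arg(test)
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  if (test == "welch_t") {
    if (length(values_a) < 2 || length(values_b) < 2)
      stop("welch_t needs at least 2 values per group")
    ht <- stats::t.test(values_a, values_b, var.equal = FALSE)
  } else {
    if (!length(values_a) || !length(values_b))
      stop("mann_whitney needs at least 1 value per group")
    ht <- suppressWarnings(
      stats::wilcox.test(values_a, values_b, exact = FALSE, correct = TRUE))
  }
  list(test = test, statistic = unname(ht$statistic), p = ht$p.value)
}

#' All pairwise group comparisons of one parameter
#'
#' @param clinical data frame with a `group` column.
#' @param parameter column to compare (`"nlr"` is derived if absent).
#' @param test passed to [compare_groups()].
#' @return data frame `group_a`, `group_b`, `statistic`, `p`.
#' @export
pairwise_group_tests <- function(clinical, parameter = "nlr",
                                 test = c("welch_t", "mann_whitney")) {
  test <- match.arg(test)
  df <- clinical
  if (parameter == "nlr" && !"nlr" %in% names(df))
    df$nlr <- compute_nlr(df$neutrophil_pct, df$lymphocyte_pct)
  groups <- unique(df$group)
  combs <- utils::combn(groups, 2, simplify = FALSE)
  rows <- lapply(combs, function(gg) {
    a <- df[[parameter]][df$group == gg[1]]
    b <- df[[parameter]][df$group == gg[2]]
    r <- tryCatch(compare_groups(a, b, test),
                  error = function(e) list(statistic = NA_real_, p = NA_real_))
    data.frame(group_a = gg[1], group_b = gg[2],
               statistic = r$statistic, p = r$p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
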