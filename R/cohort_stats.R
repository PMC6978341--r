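#' Fisher's exact test on a 2x2 variance-group by tumor-class table
#'
#' Two-sided p-value under the probability-mass convention: all tables with
#' the observed margins whose hypergeometric probability does not exceed the
#' observed table's are summed (the convention of `stats::fisher.test`).
#' The sample odds ratio `a*d / (b*c)` is reported alongside; infinite or
#' zero values are flagged rather than truncated.  A table with an empty row
#' or column margin carries no association information and returns p = 1
#' with `degenerate = TRUE`.
#'
#' @param table 2x2 matrix of non-negative integer counts
#'   (rows = score group, columns = class label).
#' @return List with `statistic_name`, `p_value`, `odds_ratio`,
#'   `or_degenerate` (TRUE when the OR is 0 or infinite), `degenerate`
#'   (zero-margin flag) and `n`.
#' @examples
#' fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2))   # p = 2/252
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("table must be 2x2")
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers")
  n <- sum(table)
  if (n < 1L) stop("table must contain at least one observation")
  degenerate <- any(rowSums(table) == 0) || any(colSums(table) == 0)
  if (degenerate) {
    return(list(statistic_name = "Fisher's exact", p_value = 1,
                odds_ratio = NA_real_, or_degenerate = NA,
                degenerate = TRUE, n = n))
  }
  p <- stats::fisher.test(table)$p.value
  or <- (table[1L, 1L] * table[2L, 2L]) / (table[1L, 2L] * table[2L, 1L])
  list(statistic_name = "Fisher's exact", p_value = p,
       odds_ratio = or, or_degenerate = !is.finite(or) || or == 0,
       degenerate = FALSE, n = n)
}

#' Spearman rank correlation between variance score and stemness index
#'
#' Pairs with a missing value in either vector are dropped (pairwise
#' deletion; the stemness index is typically available for only part of a
#' cohort).  Rho is the Pearson correlation of average ranks; the p-value
#' uses the t-approximation on n - 2 degrees of freedom, adequate at cohort
#' sample sizes.  For very small n (<= 10, no ties) an exact permutation
#' p-value is available.
#'
#' @param x,y Numeric vectors of equal length (e.g. AVS and mRNAsi).
#' @param exact Use the exact permutation null (only honoured when
#'   n <= 10 and tie-free).
#' @return List with `statistic_name`, `estimate` (rho), `p_value`, `n`.
#' @export
spearman_test <- function(x, y, exact = FALSE) {
  stopifnot(length(x) == length(y))
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("rho undefined: one of the vectors is constant")
  use_exact <- exact && n <= 10L && !any(duplicated(x)) && !any(duplicated(y))
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = use_exact))
  list(statistic_name = "Spearman correlation",
       estimate = unname(ct$estimate), p_value = ct$p.value, n = n)
}

#' Wilcoxon rank-sum comparison of two groups
#'
#' Two-sided.  For small tie-free samples (n1 + n2 <= 12) the exact null
#' distribution is enumerated; otherwise the normal approximation with tie
#' and continuity corrections is used.
#'
#' @param group1,group2 Non-empty numeric vectors (e.g. mRNAsi by class).
#' @return List with `statistic_name`, `statistic` (W), `p_value`,
#'   `n` (c(n1, n2)), `exact` (which path was used).
#' @export
wilcoxon_rank_sum <- function(group1, group2) {
  group1 <- group1[!is.na(group1)]
  group2 <- group2[!is.na(group2)]
  if (!length(group1) || !length(group2))
    stop("both groups must be non-empty")
  ties <- any(duplicated(c(group1, group2)))
  use_exact <- (length(group1) + length(group2) <= 12L) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(group1, group2, exact = use_exact, correct = TRUE))
  list(statistic_name = "Wilcoxon rank-sum",
       statistic = unname(wt$statistic), p_value = wt$p.value,
       n = c(length(group1), length(group2)), exact = use_exact)
}

#' Cross-tabulate stratified score groups against tumor classes
#'
#' Convenience join of a [stratify()] result with a clinical table, giving
#' the 2x2 table consumed by [fisher_exact_2x2()].  Classes other than the
#' two requested are dropped.
#'
#' @param groups Data frame from [stratify()].
#' @param clinical Data frame from [read_clinical()].
#' @param classes Length-2 character vector of class labels to compare.
#' @return 2x2 integer matrix, rows = group (high, low), columns = classes.
#' @export
group_class_table <- function(groups, clinical,
                              classes = c("HPV16+/p53WT", "HPV-/p53HRmut")) {
  stopifnot(length(classes) == 2L)
  merged <- merge(groups, clinical, by = "sample_id")
  merged <- merged[merged$class_label %in% classes, ]
  tab <- table(factor(merged$group, levels = c("high", "low")),
               factor(merged$class_label, levels = classes))
  matrix(as.integer(tab), 2L, 2L,
         dimnames = list(c("high", "low"), classes))
}
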