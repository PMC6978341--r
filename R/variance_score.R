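#' Convert raw family expression to percent-of-family-total
#'
#' Each member's expression is divided by the family total and scaled to
#' percent, so that a sample's profile sums to 100 regardless of sequencing
#' depth or overall family abundance.  The conversion requires linear-scale
#' input (RSEM-like); percent shares of log-transformed values are not
#' meaningful.
#'
#' @param values Non-negative numeric vector of length family-size, one
#'   entry per family member for a single sample.
#' @return Numeric vector of percents summing to 100, same names as input.
#' @examples
#' percent_of_family(c(300, 100, 0, 0))   # 75, 25, 0, 0
#' @export
percent_of_family <- function(values) {
  if (!is.numeric(values) || length(values) < 1L)
    stop("values must be a non-empty numeric vector")
  if (anyNA(values)) stop("values must not contain NA")
  if (any(values < 0)) stop("negative expression value in family profile")
  total <- sum(values)
  if (total == 0)
    stop(structure(
      class = c("famvar_undefined_profile", "error", "condition"),
      list(message = "undefined profile: all family members have zero expression",
           call = sys.call(-1))))
  100 * values / total
}

#' Family variance score of a percent profile
#'
#' The score is the population variance (divide by n, not n - 1) of the
#' percent-of-family profile:
#' \deqn{AVS = \sum_{i=1}^{n} (x_i - \bar x)^2 / n}
#' with \eqn{x} on the 0–100 percent scale and \eqn{n} the full family size
#' including zero-expression members.  A uniform profile scores 0; a profile
#' concentrated in one member attains the maximum
#' \eqn{100^2 (n-1)/n^2} (about 498.6 for the 19-member ALDH family).
#' High scores therefore flag samples dominated by a single family member.
#'
#' @param percents Percent profile as returned by [percent_of_family()].
#' @return Single non-negative number, percent-squared units.
#' @examples
#' avs(percent_of_family(rep(10, 19)))          # 0
#' avs(percent_of_family(c(1, rep(0, 18))))     # 10000 * 18 / 361
#' @export
avs <- function(percents) {
  if (!is.numeric(percents) || length(percents) < 2L)
    stop("percents must be a numeric vector of length >= 2")
  if (anyNA(percents)) stop("percents must not contain NA")
  if (abs(sum(percents) - 100) > 1e-6)
    stop("percents must sum to 100; did you call percent_of_family()?")
  mean((percents - mean(percents))^2)
}

#' Score every sample of an expression matrix against a gene family
#'
#' @param matrix Samples-by-genes numeric matrix
#'   (see [read_expression_matrix()]).
#' @param family A [gene_family()] object.
#' @param missing_policy `"error"` (default) fails when a family member is
#'   absent from the matrix, surfacing silent symbol mismatches; `"zero"`
#'   imputes absent members as zero expression and records the count.
#' @return A data frame with one row per scorable sample and columns
#'   `sample_id`, `avs`, `n_members`, `n_missing_in_matrix`.  Samples whose
#'   family total is zero cannot be scored; their ids are attached as
#'   attribute `"undefined_samples"` and a warning is raised.
#' @export
score_cohort <- function(matrix, family,
                         missing_policy = c("error", "zero")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(family, "gene_family"), is.matrix(matrix))
  members <- family$members
  absent <- setdiff(members, colnames(matrix))
  if (length(absent) && missing_policy == "error")
    stop("family members missing from matrix: ",
         paste(absent, collapse = ", "),
         " (use missing_policy = \"zero\" to impute as 0)")
  sub <- matrix(0, nrow = nrow(matrix), ncol = length(members),
                dimnames = list(rownames(matrix), members))
  present <- intersect(members, colnames(matrix))
  sub[, present] <- matrix[, present, drop = FALSE]

  totals <- rowSums(sub)
  undefined <- rownames(sub)[totals == 0]
  if (length(undefined))
    warning("samples with zero family expression excluded from scoring: ",
            paste(undefined, collapse = ", "))
  keep <- totals > 0
  scores <- apply(sub[keep, , drop = FALSE], 1L,
                  function(v) avs(percent_of_family(v)))
  out <- data.frame(
    sample_id = rownames(sub)[keep],
    avs = as.numeric(scores),
    n_members = length(members),
    n_missing_in_matrix = length(absent),
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "undefined_samples") <- undefined
  attr(out, "family") <- family$name
  out
}

#' Stratify scored samples into high and low variance groups
#'
#' Two rules mirror common cohort splits: `"median"` assigns samples at or
#' below the cohort median score to `"low"` and the rest to `"high"`;
#' `"quartile25"` assigns samples strictly below the 25th percentile
#' (linear interpolation between order statistics) to `"low"` so that
#' `"high"` holds the top 75%.  Ties at the median go to `"low"` — a
#' deterministic, documented convention.
#'
#' @param scores Data frame from [score_cohort()] (columns `sample_id`,
#'   `avs`), or any data frame with those columns.
#' @param rule `"median"` or `"quartile25"`.
#' @return Data frame with columns `sample_id`, `group` (`"high"`/`"low"`),
#'   `rule`, `threshold_value`.
#' @export
stratify <- function(scores, rule = c("median", "quartile25")) {
  rule <- match.arg(rule)
  stopifnot(is.data.frame(scores),
            all(c("sample_id", "avs") %in% colnames(scores)))
  x <- scores$avs
  if (length(x) < 2L) stop("need at least 2 scored samples to stratify")
  if (length(unique(x)) == 1L) {
    warning("degenerate stratification: all scores identical; every sample 'low'")
    threshold <- x[1L]
    group <- rep("low", length(x))
  } else if (rule == "median") {
    threshold <- stats::median(x)
    group <- ifelse(x <= threshold, "low", "high")
  } else {
    threshold <- unname(stats::quantile(x, 0.25, type = 7))
    group <- ifelse(x < threshold, "low", "high")
  }
  data.frame(sample_id = scores$sample_id, group = group,
             rule = rule, threshold_value = threshold,
             stringsAsFactors = FALSE, row.names = NULL)
}
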