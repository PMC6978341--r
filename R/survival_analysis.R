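#' Truncate follow-up at a fixed horizon
#'
#' Subjects followed beyond the horizon are administratively censored at the
#' horizon; everyone else is unchanged.  Five-year analyses use
#' `horizon = 60` months.
#'
#' @param time Non-negative follow-up times, months.
#' @param event Binary event indicators (1 = event, 0 = censored).
#' @param horizon Positive truncation time, months.
#' @return List with truncated `time` and `event` vectors.
#' @export
truncate_followup <- function(time, event, horizon = 60) {
  stopifnot(length(time) == length(event), horizon > 0)
  over <- !is.na(time) & time > horizon
  event[over] <- 0
  time[over] <- horizon
  list(time = time, event = event)
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator over the distinct event times.  Censoring is
#' handled right-continuously: a subject censored at `t` remains at risk
#' through `t`.  Without censoring the curve equals the empirical survival
#' function.
#'
#' @param time,event Follow-up times (months) and event indicators.
#' @return An object of class `km_curve`: data frame with columns `time`,
#'   `n_risk`, `n_event`, `n_censor`, `survival`.
#' @export
km_estimate <- function(time, event) {
  stopifnot(length(time) == length(event), length(time) >= 1L)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "none")
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    survival = fit$surv)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' @param curve A `km_curve` from [km_estimate()].
#' @param times Times at which to read off survival (step function,
#'   right-continuous; survival is 1 before the first event).
#' @return Numeric vector of survival probabilities.
#' @export
km_survival_at <- function(curve, times) {
  steps <- curve[curve$n_event > 0, , drop = FALSE]
  vapply(times, function(t) {
    idx <- steps$time <= t
    if (!any(idx)) 1 else steps$survival[max(which(idx))]
  }, numeric(1L))
}

#' Two-group log-rank test
#'
#' The standard log-rank statistic \eqn{(O_1 - E_1)^2 / V} with
#' hypergeometric variance summed over distinct event times; p-value from
#' the chi-square distribution with 1 df.  A dataset with no events carries
#' no information and returns statistic 0, p = 1 with a degenerate flag.
#'
#' @param time,event Follow-up times and event indicators.
#' @param group Two-level grouping vector (factor, character or binary).
#' @return List with `chisq`, `df`, `p_value`, `observed`, `expected`
#'   (per-group event counts) and `degenerate`.
#' @export
logrank_test <- function(time, event, group) {
  stopifnot(length(time) == length(event), length(time) == length(group))
  group <- factor(group)
  if (nlevels(group) != 2L) stop("group must have exactly 2 levels")
  if (min(table(group)) < 1L) stop("both groups must be non-empty")
  if (sum(event) == 0) {
    z <- c(0, 0); names(z) <- levels(group)
    return(list(chisq = 0, df = 1L, p_value = 1,
                observed = z, expected = z, degenerate = TRUE))
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  obs <- sd$obs; exp <- sd$exp
  names(obs) <- names(exp) <- levels(group)
  list(chisq = unname(sd$chisq), df = 1L,
       p_value = stats::pchisq(sd$chisq, df = 1L, lower.tail = FALSE),
       observed = obs, expected = exp, degenerate = FALSE)
}

#' Univariate Cox proportional-hazards fit for a continuous covariate
#'
#' Maximizes the Cox partial likelihood with the Efron approximation for
#' tied event times (better than Breslow for month-resolution registry
#' data; switchable).  Reports the hazard ratio per unit covariate with a
#' 95% Wald confidence interval from the observed information.
#'
#' @param covariate Numeric covariate, one value per subject.
#' @param time,event Follow-up times and event indicators.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return List with `beta`, `hr`, `se`, `ci_lower`, `ci_upper`, `p_value`
#'   (Wald), `score_chisq` (score test at beta = 0), `n`, `events`, `ties`.
#' @export
cox_univariate <- function(covariate, time, event, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  stopifnot(length(covariate) == length(time), length(time) == length(event))
  if (length(time) < 2L) stop("need at least 2 subjects")
  if (sum(event) < 1L) stop("need at least 1 event")
  if (length(unique(covariate)) == 1L)
    stop("constant covariate: hazard ratio is not identifiable")
  fit <- survival::coxph(survival::Surv(time, event) ~ covariate,
                         ties = ties,
                         control = survival::coxph.control(eps = 1e-10,
                                                           iter.max = 100))
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(fit$var[1L, 1L]))
  if (!is.finite(beta) || !is.finite(se) || abs(beta) * se > 1e4 ||
      abs(beta) > 50)
    stop("monotone partial likelihood (perfect separation): ",
         "the hazard ratio diverges; beta = ", format(beta))
  z <- stats::qnorm(0.975)
  sm <- summary(fit)
  list(beta = beta, hr = exp(beta), se = se,
       ci_lower = exp(beta - z * se), ci_upper = exp(beta + z * se),
       p_value = unname(sm$coefficients[1L, "Pr(>|z|)"]),
       score_chisq = unname(sm$sctest["test"]),
       n = length(time), events = sum(event), ties = ties)
}

#' Per-member Cox scan of a gene family, by tumor class
#'
#' Fits [cox_univariate()] for every family member as a continuous
#' covariate, separately within each tumor class, after truncating
#' follow-up at `horizon`.  The covariate scale defaults to
#' `log2(expression + 1)` per unit — hazard ratios on a raw RSEM scale are
#' dominated by high-abundance members and are rarely comparable across
#' genes; the scale used is recorded in the output attributes.
#'
#' @param matrix Samples-by-genes expression matrix.
#' @param family A [gene_family()].
#' @param clinical Clinical data frame (see [read_clinical()]).
#' @param transform `"log2p1"` (default) or `"raw"`.
#' @param horizon Follow-up truncation, months (default 60 = five years).
#' @param missing_policy Passed through to member lookup: `"error"` or
#'   `"zero"`.
#' @return Data frame with columns `class_label`, `gene`, `hr`, `ci_lower`,
#'   `ci_upper`, `p_value`, `n`, `events`.  Members that cannot be fit in a
#'   cohort (fewer than 2 events, constant covariate, diverging fit) are
#'   skipped with a warning.
#' @export
cox_family_scan <- function(matrix, family, clinical,
                            transform = c("log2p1", "raw"), horizon = 60,
                            missing_policy = c("error", "zero")) {
  transform <- match.arg(transform)
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(family, "gene_family"))
  absent <- setdiff(family$members, colnames(matrix))
  if (length(absent) && missing_policy == "error")
    stop("family members missing from matrix: ", paste(absent, collapse = ", "))
  common <- intersect(rownames(matrix), clinical$sample_id)
  clin <- clinical[match(common, clinical$sample_id), ]
  tr <- truncate_followup(clin$time, clin$event, horizon)

  rows <- list()
  for (cl in unique(clin$class_label)) {
    in_cl <- clin$class_label == cl
    if (sum(tr$event[in_cl]) < 2L) {
      warning("cohort '", cl, "' has fewer than 2 events; all members skipped")
      next
    }
    for (g in family$members) {
      expr <- if (g %in% colnames(matrix)) matrix[common, g] else rep(0, length(common))
      x <- if (transform == "log2p1") log2(expr + 1) else expr
      res <- tryCatch(
        cox_univariate(x[in_cl], tr$time[in_cl], tr$event[in_cl]),
        error = function(e) {
          warning("skipping ", g, " in cohort '", cl, "': ",
                  conditionMessage(e))
          NULL
        })
      if (!is.null(res))
        rows[[length(rows) + 1L]] <- data.frame(
          class_label = cl, gene = g, hr = res$hr,
          ci_lower = res$ci_lower, ci_upper = res$ci_upper,
          p_value = res$p_value, n = res$n, events = res$events,
          stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(class_label = character(), gene = character(),
               hr = numeric(), ci_lower = numeric(), ci_upper = numeric(),
               p_value = numeric(), n = integer(), events = integer())
  rownames(out) <- NULL
  attr(out, "covariate_scale") <- transform
  attr(out, "horizon") <- horizon
  out
}
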