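test_that("follow-up truncation censors at the horizon", {
  tr <- truncate_followup(c(70, 50), c(1, 1), horizon = 60)
  expect_equal(tr$time, c(60, 50))
  expect_equal(tr$event, c(0, 1))
  tr2 <- truncate_followup(numeric(0), numeric(0))
  expect_length(tr2$time, 0)
  expect_error(truncate_followup(1, 1, horizon = 0))
})

test_that("Kaplan-Meier equals empirical survival without censoring", {
  km <- km_estimate(1:5, rep(1, 5))
  expect_equal(km$survival, c(0.8, 0.6, 0.4, 0.2, 0))
  set.seed(21)
  t <- round(rexp(40, 0.1), 3)
  km2 <- km_estimate(t, rep(1, 40))
  emp <- sapply(km2$time, function(s) mean(t > s))
  expect_equal(km2$survival, emp, tolerance = 1e-12)
})

test_that("Kaplan-Meier handles censoring right-continuously", {
  expect_equal(km_estimate(c(3, 1, 8), rep(0, 3))$survival, rep(1, 3))
  # subject censored at 2 is not at risk at the t = 3 event:
  # S(1) = 2/3, S(3) = (2/3) * (1 - 1/1) = 0
  km <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km_survival_at(km, c(0.5, 1, 2.5, 3)), c(1, 2/3, 2/3, 0))
  # censored exactly at an event time stays at risk through it
  km2 <- km_estimate(c(1, 1, 2), c(1, 0, 1))
  expect_equal(km_survival_at(km2, 1), 2/3)
})

test_that("log-rank statistic matches the per-event-time O/E/V oracle", {
  set.seed(31)
  t <- c(2, 5, 7, 1, 8, 9); e <- c(1, 1, 0, 1, 1, 1); g <- c(0, 0, 0, 1, 1, 1)
  res <- logrank_test(t, e, g)
  expect_equal(res$chisq, oracle_logrank_chisq(t, e, g), tolerance = 1e-9)
  expect_equal(sum(res$observed), sum(res$expected), tolerance = 1e-9)
  expect_equal(res$p_value, pchisq(res$chisq, 1, lower.tail = FALSE))

  for (i in 1:20) {
    n <- 12
    t <- round(rexp(n, 0.1), 2); e <- rbinom(n, 1, 0.7); g <- rbinom(n, 1, 0.5)
    if (sum(e) == 0 || length(unique(g)) < 2) next
    res <- logrank_test(t, e, g)
    expect_equal(res$chisq, oracle_logrank_chisq(t, e, g), tolerance = 1e-8)
    # label symmetry
    expect_equal(logrank_test(t, e, 1 - g)$chisq, res$chisq, tolerance = 1e-12)
  }
})

test_that("identical groups and event-free data give degenerate log-rank", {
  t <- c(1, 2, 3, 1, 2, 3); e <- c(1, 1, 0, 1, 1, 0); g <- rep(0:1, each = 3)
  res <- logrank_test(t, e, g)
  expect_equal(res$chisq, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1)

  res0 <- logrank_test(c(1, 2), c(0, 0), c(0, 1))
  expect_true(res0$degenerate)
  expect_equal(res0$chisq, 0)
  expect_equal(res0$p_value, 1)
})

test_that("Cox fit maximizes the partial likelihood (tie-free oracle)", {
  set.seed(41)
  n <- 8
  t <- c(1.1, 2.3, 3.7, 4.1, 5.9, 6.2, 7.8, 9.4)
  e <- c(1, 1, 0, 1, 1, 0, 1, 1)
  x <- c(0.2, -1.1, 0.7, 1.9, -0.4, 0.1, 1.3, -2.2)
  fit <- cox_univariate(x, t, e)
  expect_equal(fit$beta, oracle_cox_beta(x, t, e), tolerance = 1e-6)
  expect_true(fit$ci_lower <= fit$hr && fit$hr <= fit$ci_upper)
  # sign reparameterization: HR(-x) = 1/HR(x)
  fit_neg <- cox_univariate(-x, t, e)
  expect_equal(fit_neg$hr, 1 / fit$hr, tolerance = 1e-8)
})

test_that("Cox score test equals the log-rank statistic for binary covariates", {
  set.seed(51)
  for (i in 1:10) {
    n <- 25
    t <- round(rexp(n, 0.05), 4)   # continuous, tie-free w.p. 1
    e <- rbinom(n, 1, 0.8); g <- rbinom(n, 1, 0.5)
    if (sum(e) < 2 || length(unique(g)) < 2 || anyDuplicated(t)) next
    expect_equal(cox_univariate(g, t, e)$score_chisq,
                 logrank_test(t, e, g)$chisq, tolerance = 1e-6)
  }
})

test_that("Cox error contracts: constant covariate, separation, tiny data", {
  expect_error(cox_univariate(rep(0, 5), 1:5, rep(1, 5)), "constant")
  expect_error(cox_univariate(1:2, 1:2, c(0, 0)), "at least 1 event")
  # perfect separation: covariate order equals event-time order
  t <- 1:12; e <- rep(1, 12); x <- 12:1
  expect_error(suppressWarnings(cox_univariate(x, t, e)),
               "monotone|separation")
})

test_that("null-covariate Cox confidence intervals cover HR = 1", {
  set.seed(61)
  cover <- 0; total <- 200
  for (i in 1:total) {
    n <- 60
    x <- rnorm(n)
    te <- rexp(n, 0.02); tc <- runif(n, 0, 100)
    fit <- cox_univariate(x, pmin(te, tc), as.integer(te <= tc))
    cover <- cover + (fit$ci_lower <= 1 && 1 <= fit$ci_upper)
  }
  expect_gte(cover / total, 0.90)
})

test_that("family-wide Cox scan yields one row per member per class", {
  fam <- gene_family("DEMO", c("G1", "G2", "G3"))
  cfg <- synthetic_config(n_per_class = 60, family = fam,
                          alpha_dominant = c(5, 0.5, 0.5),
                          alpha_diverse = rep(2, 3), seed = 71)
  co <- generate_cohort(cfg)
  scan <- cox_family_scan(co$matrix, fam, co$clinical)
  expect_identical(sort(unique(scan$gene)), c("G1", "G2", "G3"))
  expect_identical(attr(scan, "covariate_scale"), "log2p1")
  expect_true(all(scan$ci_lower <= scan$hr & scan$hr <= scan$ci_upper))
  expect_true(all(scan$hr > 0))

  # a cohort of 1 sample has < 2 events: every member skipped
  clin1 <- co$clinical[1, ]
  expect_warning(scan1 <- cox_family_scan(co$matrix[1, , drop = FALSE],
                                          fam, clin1),
                 "fewer than 2 events")
  expect_identical(nrow(scan1), 0L)
})
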