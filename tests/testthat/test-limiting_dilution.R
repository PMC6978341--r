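test_that("single-dose fits reproduce the closed form", {
  a <- dilution_assay(1000, 10, 4)
  fit <- fit_single_hit(a)
  expect_equal(fit$f, -log(1 - 0.4) / 1000, tolerance = 1e-10)
  expect_identical(fit$reciprocal, "1/1,958")
  expect_identical(fit$boundary, "none")
  # spot-check a spread of (k, n); the full 1 <= k < n <= 50 sweep runs in
  # the acceptance suite
  for (n in c(5, 12, 37)) for (k in c(1, n %/% 2, n - 1)) {
    f <- fit_single_hit(dilution_assay(500, n, k))$f
    expect_equal(f, -log(1 - k / n) / 500, tolerance = 1e-10)
  }
})

test_that("multi-dose MLE matches a dense grid search of the likelihood", {
  a <- dilution_assay(c(1e3, 1e4, 1e5), c(10, 10, 10), c(2, 6, 10))
  fit <- fit_single_hit(a)
  grid <- exp(seq(log(1e-7), log(1e-2), length.out = 1e6))
  ll <- vapply(grid, oracle_single_hit_loglik, numeric(1),
               dose = a$dose, n = a$tested, k = a$responding)
  expect_equal(fit$f, grid[which.max(ll)], tolerance = 1e-5)
  expect_gte(fit$loglik, max(ll) - 1e-9)
})

test_that("estimate agrees with the complementary-log-log GLM formulation", {
  set.seed(81)
  for (i in 1:10) {
    a <- simulate_assay(10^runif(1, -5, -3), c(1e3, 1e4, 1e5), 10, seed = i)
    if (all(a$responding == 0) || all(a$responding == a$tested)) next
    fit <- fit_single_hit(a)
    # saturated doses make glm warn about fitted p ~ 1; harmless for an oracle
    g <- suppressWarnings(
      glm(cbind(responding, tested - responding) ~ 1 + offset(log(dose)),
          family = binomial("cloglog"), data = a))
    expect_equal(log(fit$f), unname(coef(g)), tolerance = 1e-6)
  }
})

test_that("dose scaling transforms the frequency reciprocally", {
  a <- dilution_assay(c(100, 1000, 10000), c(8, 8, 8), c(1, 4, 7))
  f1 <- fit_single_hit(a)$f
  b <- dilution_assay(a$dose * 10, a$tested, a$responding)
  expect_equal(fit_single_hit(b)$f, f1 / 10, tolerance = 1e-9)
})

test_that("boundary assays are flagged with one-sided bounds", {
  none <- fit_single_hit(dilution_assay(c(1e3, 1e4), c(5, 5), c(0, 0)))
  expect_identical(none$boundary, "lower")
  expect_equal(none$f, 0)
  expect_gt(none$ci_upper, 0)
  expect_equal(none$ci_upper, -log(0.05) / (5 * 1e3 + 5 * 1e4),
               tolerance = 1e-12)

  all_took <- fit_single_hit(dilution_assay(c(1e3, 1e4), c(5, 5), c(5, 5)))
  expect_identical(all_took$boundary, "upper")
  expect_lt(all_took$ci_lower, 1)
  expect_error(fit_single_hit(data.frame(dose = numeric(0),
                                         tested = integer(0),
                                         responding = integer(0))),
               "at least one dose")
})

test_that("profile and Wald intervals both bracket the MLE", {
  a <- dilution_assay(c(1e3, 1e4, 1e5), c(10, 10, 10), c(3, 7, 10))
  w <- fit_single_hit(a, ci = "wald")
  p <- fit_single_hit(a, ci = "profile")
  expect_equal(w$f, p$f)
  for (fit in list(w, p)) {
    expect_lt(fit$ci_lower, fit$f)
    expect_gt(fit$ci_upper, fit$f)
  }
})

test_that("arm comparison: identical arms are null, distinct arms detected", {
  a <- dilution_assay(c(1e3, 1e4), c(10, 10), c(3, 8), arm = "control")
  same <- compare_arms(a, a)
  expect_equal(same$lr_chisq, 0, tolerance = 1e-8)
  expect_equal(same$p_value, 1, tolerance = 1e-6)
  expect_equal(same$fold, 1, tolerance = 1e-9)

  b <- dilution_assay(c(1e3, 1e4), c(10, 10), c(0, 1), arm = "knockdown")
  diff <- compare_arms(a, b)
  expect_gt(diff$fold, 1)
  expect_lt(diff$p_value, 0.05)
})

test_that("a true 10-fold frequency difference is recovered in the median", {
  folds <- vapply(1:200, function(s) {
    a <- simulate_assay(1e-3, c(1e3, 1e4, 1e5), 10, seed = 1000 + s)
    b <- simulate_assay(1e-4, c(1e3, 1e4, 1e5), 10, seed = 2000 + s)
    if (all(a$responding == a$tested) && all(b$responding == b$tested))
      return(NA_real_)
    compare_arms(a, b)$fold
  }, numeric(1))
  expect_gt(median(folds, na.rm = TRUE), 7)
  expect_lt(median(folds, na.rm = TRUE), 14)
})

test_that("assay simulation is seeded, saturating and degenerate-safe", {
  expect_identical(simulate_assay(1e-4, c(1e3, 1e4), 10, seed = 3),
                   simulate_assay(1e-4, c(1e3, 1e4), 10, seed = 3))
  zero <- simulate_assay(0, c(1e3, 1e4), 10, seed = 4)
  expect_true(all(zero$responding == 0))
  sat <- simulate_assay(0.02, 1000, 50, seed = 5)  # d*f = 20: saturation
  expect_identical(sat$responding, sat$tested)
})

test_that("assay tables read per arm and frequencies format as 1/N", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("arm\tdose\ttested\tresponding",
               "control\t1000\t5\t3",
               "control\t10000\t5\t5",
               "knockdown\t1000\t5\t0",
               "knockdown\t10000\t5\t1"), tf)
  arms <- read_dilution_assay(tf)
  expect_identical(names(arms), c("control", "knockdown"))
  expect_s3_class(arms$control, "dilution_assay")
  expect_identical(reciprocal_label(1 / 9205), "1/9,205")
  expect_identical(reciprocal_label(0), "0")
})
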