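test_that("Cohen's d matches hand-computed pooled-SD values and its invariances", {
  expect_equal(round(cohens_d(38.16, 13.89, 80, 33.24, 12.31, 86), 2), 0.38)
  expect_equal(cohens_d(5, 1, 10, 5, 1, 10), 0)
  # symmetry in group order and scale invariance
  d1 <- cohens_d(10, 2, 30, 12, 3, 40)
  expect_equal(cohens_d(12, 3, 40, 10, 2, 30), d1)
  expect_equal(cohens_d(100, 20, 30, 120, 30, 40), d1)
  expect_error(cohens_d(1, 0, 10, 1, 0, 10), "pooled SD")
  expect_error(cohens_d(1, 1, 1, 2, 1, 10), ">= 2")
})

test_that("Bonferroni thresholds divide the base alpha by the family size", {
  expect_equal(bonferroni_alpha(0.05, 2), 0.025)
  expect_equal(bonferroni_alpha(0.05, 5), 0.01)
  expect_equal(round(bonferroni_alpha(0.05, 3), 3), 0.017)
  expect_error(bonferroni_alpha(0.05, 0), ">= 1")
})

test_that("HR adjustment follows the correlation sign rule", {
  set.seed(21)
  n <- 60
  hr <- rnorm(n, 90, 10)
  coh <- data.frame(
    sex_code = rep(1:2, each = n / 2),
    hr = hr,
    neg = 50 - 0.3 * hr + rnorm(n, 0, 2), # negatively HR-correlated
    pos = 1 + 0.01 * hr + rnorm(n, 0, 0.02)) # like short-term DFA
  adj <- hr_adjust(coh, c("neg", "pos"))
  expect_equal(adj$report$operation, c("divided_by_hr", "multiplied_by_hr"))
  expect_equal(adj$cohort$neg_adj, coh$neg / coh$hr)
  expect_equal(adj$cohort$pos_adj, coh$pos * coh$hr)

  # exactly-zero correlation: left unadjusted, with a warning
  coh0 <- data.frame(hr = c(80, 90, 100), m = c(1, 2, 1))
  expect_warning(adj0 <- hr_adjust(coh0, "m"), "unadjusted")
  expect_equal(adj0$cohort$m_adj, coh0$m)

  # zero-variance measure: correlation undefined, unadjusted with warning
  cohc <- data.frame(hr = c(80, 90, 100), m = c(2, 2, 2))
  expect_warning(hr_adjust(cohc, "m"), "unadjusted")
})

test_that("two-group comparison F equals the squared pooled-variance t", {
  set.seed(31)
  for (rep in 1:20) {
    coh <- data.frame(sex_code = rep(1:2, c(12, 15)),
                      m = rnorm(27, 10, 2))
    res <- compare_groups(coh, "m")
    tt <- t.test(m ~ sex_code, data = coh, var.equal = TRUE)
    expect_equal(res$f, unname(tt$statistic)^2, tolerance = 1e-9)
    expect_equal(res$p, tt$p.value, tolerance = 1e-9)
    expect_equal(res$df1, 1)
    expect_equal(res$df2, 25)
  }
})

test_that("identical groups give F = 0 and d = 0", {
  x <- rnorm(20, 5, 1)
  coh <- data.frame(sex_code = rep(1:2, each = 20), m = c(x, x))
  res <- compare_groups(coh, "m")
  expect_equal(res$f, 0, tolerance = 1e-12)
  expect_equal(res$cohens_d, 0)
  expect_false(res$significant)
  expect_error(compare_groups(data.frame(sex_code = rep(1, 10),
                                         m = rnorm(10)), "m"),
               "two levels")
})

test_that("group comparisons recover a true standardized difference of 0.5", {
  set.seed(41)
  d_hat <- vapply(1:200, function(i) {
    coh <- data.frame(sex_code = rep(1:2, c(80, 86)),
                      m = c(rnorm(80, 0.5), rnorm(86, 0)))
    compare_groups(coh, "m")$cohens_d
  }, numeric(1))
  expect_equal(mean(d_hat), 0.5, tolerance = 0.05)
})

test_that("hierarchical regression recovers generative structure", {
  set.seed(51)
  n <- 166
  sex <- rep(1:2, c(80, 86))
  # pure sex effect, no measure effect
  m <- rnorm(n)
  y <- 2 * sex + rnorm(n)
  coh <- data.frame(sex_code = sex, m = m, y = y)
  fit <- hierarchical_regression(coh, "y", "m")
  expect_lt(fit$step1$coef$p[fit$step1$coef$term == "sex"], 0.001)
  expect_lt(abs(fit$step1$coef$beta[fit$step1$coef$term == "z"]), 0.15)
  expect_equal(fit$step1$r2, fit$step1$delta_r2)
  expect_gte(fit$step2$delta_r2, 0)

  # a true interaction inflates the step-2 increment
  y_int <- 1 + 0.8 * (sex - 1.5) * m + rnorm(n)
  coh$y_int <- y_int
  d_with <- hierarchical_regression(coh, "y_int", "m")$step2$delta_r2
  d_without <- hierarchical_regression(coh, "y", "m")$step2$delta_r2
  expect_gt(d_with, d_without)

  # standardized betas are invariant to rescaling the raw measure
  coh$m_k <- coh$m * 1000
  f1 <- hierarchical_regression(coh, "y", "m")
  f2 <- hierarchical_regression(coh, "y", "m_k")
  expect_equal(f1$step2$coef$beta, f2$step2$coef$beta, tolerance = 1e-10)

  # single-sex cohort: interaction design is rank deficient
  expect_error(hierarchical_regression(
    data.frame(sex_code = rep(2, 30), m = rnorm(30), y = rnorm(30)),
    "y", "m"), "collinear")
})

test_that("listwise deletion drops incomplete rows only", {
  set.seed(61)
  coh <- data.frame(sex_code = rep(1:2, each = 30), m = rnorm(60),
                    y = rnorm(60))
  coh$y[c(3, 7, 40)] <- NA
  fit <- hierarchical_regression(coh, "y", "m")
  expect_equal(fit$n, 57)
})
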