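test_that("six-group assignment follows the precedence rule", {
  expect_equal(assign_six_groups("GCB", "High", "HR"), "GCB/MYC-high")
  expect_equal(assign_six_groups("GCB", "Low", "HR"), "GCB/HR")
  expect_equal(assign_six_groups("GCB", "Low", "non-HR"), "GCB/non-HR")
  expect_equal(assign_six_groups("ABC", "Low", "HR"), "ABC/MYC-low")
  expect_equal(assign_six_groups("ABC", "High", "non-HR"), "ABC/MYC-high")
  expect_equal(assign_six_groups("Unclassified", "High", "HR"),
               "COO-Unclassified")
  expect_true(is.na(assign_six_groups("GCB", NA, "HR")))
  expect_true(is.na(assign_six_groups("GCB", "Low", NA)))
  # Unclassified needs no other component
  expect_equal(assign_six_groups("Unclassified", NA, NA),
               "COO-Unclassified")
})

test_that("six-group table counts sum to n and every triple maps once", {
  coo <- rep(c("GCB", "ABC", "Unclassified"), times = c(10, 6, 4))
  myc <- rep(c("High", "Low"), 10)
  monti <- rep(c("HR", "non-HR"), each = 10)
  groups <- assign_six_groups(coo, myc, monti)
  tab <- six_group_table(groups)
  expect_equal(sum(tab$n), 20)
  expect_equal(sort(unique(groups)) %in% tab$group, rep(TRUE, length(unique(groups))))
})

test_that("proportions round half-up at the printed precision", {
  expect_equal(proportion(45, 58, 1), 77.6)
  expect_equal(proportion(73, 94, 1), 77.7)
  expect_equal(proportion(0, 10), 0)
  expect_equal(proportion(1, 8, 0), 13)   # 12.5 rounds up, not to even
  expect_error(proportion(1, 0), "positive")
})

test_that("Fisher's exact test matches hypergeometric enumeration", {
  t1 <- matrix(c(1, 0, 0, 1), 2, 2)
  expect_equal(fisher_exact(t1)$p_value, 1.0)
  t2 <- matrix(c(5, 0, 0, 5), 2, 2)
  expect_equal(fisher_exact(t2)$p_value, 2 / 252)
  expect_equal(fisher_exact(t2)$p_value, fisher_enum_p(t2))
  expect_error(fisher_exact(matrix(c(-1, 0, 0, 1), 2, 2)), "non-negative")
})

test_that("Fisher p equals the enumeration oracle on all tables up to n = 20", {
  for (n in 1:20) {
    for (a in 0:n) for (b in 0:(n - a)) for (cc in 0:(n - a - b)) {
      tab <- matrix(c(a, cc, b, n - a - b - cc), 2, 2)
      expect_equal(fisher_exact(tab)$p_value, fisher_enum_p(tab),
                   tolerance = 1e-9,
                   info = paste(tab, collapse = ","))
    }
  }
})

test_that("odds ratio is the sample cross-product with zero conventions", {
  expect_equal(fisher_exact(matrix(c(45, 21, 13, 73), 2, 2))$odds_ratio,
               45 * 73 / (13 * 21))
  expect_equal(fisher_exact(matrix(c(5, 0, 0, 5), 2, 2))$odds_ratio, Inf)
  expect_true(is.nan(fisher_exact(matrix(c(0, 0, 0, 5), 2, 2))$odds_ratio))
})

test_that("chi-square is the uncorrected Pearson statistic", {
  even <- matrix(c(10, 10, 10, 10), 2, 2)
  res <- chi2_test(even)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  diag2 <- matrix(c(10, 0, 0, 10), 2, 2)
  res2 <- chi2_test(diag2)
  expect_equal(res2$statistic, 20)
  expect_equal(res2$df, 1)

  big <- matrix(c(45, 21, 13, 73), 2, 2)
  res3 <- chi2_test(big)
  expect_gt(res3$statistic, 30)
  expect_lt(res3$p_value, 1e-5)

  expect_error(chi2_test(matrix(c(5, 5, 0, 0), 2, 2)), "expected")
})

test_that("confusion metrics match hand arithmetic", {
  pred <- rep(c(TRUE, FALSE, TRUE, FALSE), c(9, 1, 3, 7))
  truth <- rep(c(TRUE, TRUE, FALSE, FALSE), c(9, 1, 3, 7))
  m <- sensitivity_specificity(pred, truth)
  expect_equal(m$sensitivity, 0.9)
  expect_equal(m$specificity, 0.7)
  expect_equal(m$ppv, 0.75)
  expect_equal(m$npv, 0.875)

  same <- sensitivity_specificity(truth, truth)
  expect_equal(unlist(same), c(sensitivity = 1, specificity = 1,
                               ppv = 1, npv = 1))
  flip <- sensitivity_specificity(!truth, truth)
  expect_equal(flip$sensitivity, 0)
  expect_equal(flip$specificity, 0)
  expect_error(sensitivity_specificity(pred, rep(TRUE, 20)), "both")
})

test_that("Spearman correlation uses average ranks and pairwise deletion", {
  expect_equal(spearman(1:5, c(2, 4, 6, 8, 10)), 1)
  expect_equal(spearman(1:5, c(10, 8, 6, 4, 2)), -1)
  expect_equal(spearman(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_equal(spearman(c(1, 2, 3, NA), c(1, 3, 2, 5)), 0.5)
  expect_true(is.na(spearman(c(1, 1, 1), 1:3)))
  expect_error(spearman(c(1, 2, NA), c(1, 2, 3)), "3 complete pairs")
})

test_that("Kaplan-Meier matches the hand product-limit computation", {
  km <- km_estimate(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(km$steps$surv, c(0.75, 0.5, 0.25, 0))
  expect_equal(km$five_year_os, 0)

  censored <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(censored$steps$surv == 1))
  expect_equal(censored$five_year_os, 1)

  # moving a censoring time that falls after the last event does not
  # perturb survival at earlier times
  a <- km_estimate(c(1, 2, 3, 10), c(1, 1, 1, 0))
  b <- km_estimate(c(1, 2, 3, 50), c(1, 1, 1, 0))
  expect_equal(a$steps$surv[1:3], b$steps$surv[1:3])

  expect_error(km_estimate(c(-1, 2), c(1, 1)), "non-negative")
})

test_that("Cox fit matches brute-force partial-likelihood maximization", {
  time <- c(1, 1, 2, 3, 4, 5)  # includes a tie to exercise Efron weights
  event <- c(1, 0, 1, 1, 0, 1)
  x <- c(1, 0, 1, 0, 1, 0)
  fit <- cox_fit(time, event, data.frame(x = x))
  beta_bf <- cox_brute_force(time, event, x)
  expect_equal(fit$coef, beta_bf, tolerance = 1e-3)

  expect_error(cox_fit(c(1, 2), c(0, 0), data.frame(x = c(0, 1))),
               "2 events")
})

test_that("Cox estimates are calibrated on simulated data", {
  labels <- rep(c("a", "b"), each = 2000)
  s <- generate_survival(labels, c(a = 0.2, b = 0.2), Inf, seed = 31)
  fit_null <- cox_fit(s$time, s$event, data.frame(grp = labels == "b"))
  expect_lt(abs(fit_null$hr - 1), 0.1)

  s3 <- generate_survival(labels, c(a = 0.1, b = 0.3), Inf, seed = 32)
  fit3 <- cox_fit(s3$time, s3$event, data.frame(grp = labels == "b"))
  expect_lt(abs(fit3$coef - log(3)), 0.15)

  # univariate mode returns one row per covariate
  covs <- data.frame(grp = labels == "b", noise = rnorm(4000))
  uni <- cox_fit(s3$time, s3$event, covs, mode = "univariate")
  expect_equal(nrow(uni), 2)
})
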