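test_that("sigma_d combines standard deviations under independence", {
  expect_equal(round(sigma_diff(0.02, 0.03)$two_sigma_d, 2), 0.07)
  expect_equal(round(sigma_diff(0.01, 0.05)$two_sigma_d, 2), 0.10)
  expect_equal(sigma_diff(0.3, 0)$sigma_d, 0.3)
  expect_error(sigma_diff(-0.1, 0.2), "non-negative")
})

test_that("paired t on the published cutoffs matches the reported values", {
  pp <- novel_pairs("a")
  t1 <- paired_t(pp, n_remove = 1)
  expect_equal(t1$removed[[1]], "Clarissa")  # |d| = 50 is the outlier
  expect_equal(round(t1$t, 3), -3.091)
  t0 <- paired_t(pp, n_remove = 0)
  expect_equal(round(t0$t, 2), -3.18)
  expect_error(paired_t(paired_params(c("a", "b"), c(1, 2), c(1, 2))),
               "variance")
})

test_that("simulated t null converges to the closed-form Student t", {
  # n_remove = 0: closed-form two-sided Student-t(9) oracle
  p_exact <- 2 * stats::pt(-2.466, df = 9)
  p_sim <- simulated_t_pvalue(2.466, n = 10, n_remove = 0, n_sims = 1e5,
                              seed = 81)
  se <- sqrt(p_exact * (1 - p_exact) / 1e5)
  expect_lt(abs(p_sim - p_exact), 3 * se)
  expect_gt(simulated_t_pvalue(0, n = 10, n_sims = 1000, seed = 1), 0.95)
  expect_identical(simulated_t_pvalue(2, 10, 1, 500, seed = 4),
                   simulated_t_pvalue(2, 10, 1, 500, seed = 4))
  expect_error(simulated_t_pvalue(1, 10, n_sims = 50), "unstable")
})

test_that("outlier-removed paired t on cutoffs is significant (simulated null)", {
  pp <- novel_pairs("a")
  t1 <- paired_t(pp, n_remove = 1)
  p <- simulated_t_pvalue(t1$t, n = nrow(pp), n_remove = 1, n_sims = 2e4,
                          seed = 82)
  expect_lt(abs(p - 0.015), 0.01)
})

test_that("coin-flip test is exact and matches the published statistic", {
  pp <- novel_pairs("a")
  cf <- coin_flip_test(pp)
  expect_equal(cf$statistic, 16.9, tolerance = 1e-12)
  expect_equal(cf$n_configs, 1024L)
  expect_lte(cf$p_value, 0.05)
  expect_gte(cf$p_value, 2^-10)
  # degenerate and tiny enumerations
  same <- paired_params(c("x", "y"), c(1, 2), c(1, 2))
  cf0 <- coin_flip_test(same)
  expect_equal(cf0$statistic, 0)
  expect_equal(cf0$p_value, 1)
  two <- paired_params(c("x", "y"), c(2, 4), c(1, 2))
  cf2 <- coin_flip_test(two)
  expect_equal(cf2$statistic, 1.5)
  expect_equal(cf2$p_value, 0.5)  # 2 of the 4 sign patterns reach 1.5
})

test_that("coin-flip exact p agrees with a sign-flip Monte Carlo", {
  pp <- novel_pairs("gamma")
  cf <- coin_flip_test(pp)
  d <- pp$x - pp$y
  set.seed(83)
  n_mc <- 1e5
  signs <- matrix(sample(c(-1, 1), n_mc * length(d), replace = TRUE),
                  nrow = n_mc)
  stats_mc <- abs(signs %*% d) / length(d)
  p_mc <- mean(stats_mc >= cf$statistic - 1e-12)
  se <- sqrt(cf$p_value * (1 - cf$p_value) / n_mc)
  expect_lt(abs(p_mc - cf$p_value), 3 * se)
})

test_that("correlations reproduce the published cutoff associations", {
  nov <- ten_novels()
  expect_equal(round(cor(nov$a_w, nov$a_l), 3), 0.961)
  sp <- cor_perm_test(nov$a_w, nov$a_l / nov$a_w, method = "spearman",
                      n_perm = 2e4, seed = 84)
  expect_equal(round(sp$rho, 3), -0.867)
  expect_lt(sp$p_value, 0.02)
  pe <- cor_perm_test(nov$a_l, nov$a_w / nov$a_l, method = "pearson",
                      n_perm = 2e4, seed = 85)
  expect_equal(round(pe$rho, 3), 0.420)
  expect_gt(pe$p_value, 0.05)
})

test_that("spearman equals pearson on average ranks, including ties", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  y <- c(2, 7, 1, 8, 2, 8, 1, 8)
  s <- cor_perm_test(x, y, method = "spearman", n_perm = 10)
  expect_equal(s$rho, stats::cor(rank(x), rank(y)))
  expect_equal(s$rho, stats::cor(x, y, method = "spearman"))
  # no ties: 1 - 6 sum d^2 / (n (n^2 - 1))
  x2 <- c(1, 2, 3, 4, 5)
  y2 <- c(2, 1, 4, 3, 5)
  d2 <- rank(x2) - rank(y2)
  s2 <- cor_perm_test(x2, y2, method = "spearman", n_perm = 10)
  expect_equal(s2$rho, 1 - 6 * sum(d2^2) / (5 * 24))
  # monotone transforms: spearman 1, and pearson 1 for affine maps
  expect_equal(cor_perm_test(x2, exp(x2), method = "spearman", n_perm = 5)$rho, 1)
  expect_equal(cor_perm_test(x2, 2 * x2 + 3, method = "pearson", n_perm = 5)$rho, 1)
})

test_that("permutation p-values are exact for small N and calibrated", {
  # y = x with N = 5 and asymmetric values: only the identity permutation
  # reaches |rho| = 1 (a symmetric value set would also admit rho = -1)
  x <- c(1, 2, 4, 8, 16)
  r <- cor_perm_test(x, x, method = "pearson")
  expect_true(r$exact)
  expect_equal(r$n_resamples, 120)
  expect_equal(r$p_value, 1 / 120)
  # pearson is symmetric in its arguments under exhaustive enumeration
  y <- c(2, 1, 5, 3, 6)
  expect_equal(cor_perm_test(x, y, "pearson")$p_value,
               cor_perm_test(y, x, "pearson")$p_value)
  # null calibration at N = 10 (sampled mode): p approximately uniform
  withr::local_seed(86)
  ps <- replicate(100, {
    cor_perm_test(rnorm(10), rnorm(10), "pearson", n_perm = 400)$p_value
  })
  expect_lt(abs(mean(ps < 0.2) - 0.2), 0.12)
})

test_that("mean-independence regressions reproduce the published cutoff rows", {
  nov <- ten_novels()
  r1 <- mean_independence_regression(nov$a_l, nov$a_w)   # E[a_w | a_l]
  expect_equal(round(r1$slope, 3), 1.012)
  expect_equal(round(r1$se_slope, 3), 0.103)
  expect_equal(round(r1$intercept, 3), -17.523)
  expect_equal(round(r1$se_intercept, 3), 7.798)
  expect_equal(round(r1$t_slope_vs_1, 3), 0.115)
  expect_equal(round(r1$t_intercept_vs_0, 3), -2.247)
  r2 <- mean_independence_regression(nov$a_w, nov$a_l)   # E[a_l | a_w]
  expect_equal(round(r2$slope, 3), 0.912)
  expect_equal(round(r2$intercept, 3), 20.009)
  expect_equal(round(r2$t_slope_vs_1, 3), -0.945)
  expect_equal(round(r2$t_intercept_vs_0, 3), 3.190)
  expect_equal(round(r2$p_intercept, 3), 0.013)
  # identity: slope 1, intercept 0, reference t-statistics 0
  ident <- suppressWarnings(mean_independence_regression(1:5, 1:5 + 0))
  expect_equal(ident$slope, 1)
  expect_equal(abs(ident$t_slope_vs_1) < 1e-8, TRUE)
  # identities tying t-statistics to their standard errors
  expect_equal(r1$t_intercept_vs_0 * r1$se_intercept, r1$intercept)
  expect_equal(r1$t_slope_vs_1 * r1$se_slope, r1$slope - 1)
})

test_that("compare_texts assembles the full battery consistently", {
  cmp <- compare_texts(ten_novels(), n_sims = 2000, n_perm = 5000, seed = 87)
  expect_s3_class(cmp, "zipf_comparison")
  expect_equal(nrow(cmp$per_text), 10)
  # per-text sigma_d matches the published two-sigma column where printed
  # rounding is self-consistent (Clarissa row)
  clar <- cmp$per_text[cmp$per_text$label == "Clarissa", ]
  expect_equal(round(clar$two_sigma_d, 2), 0.07)
  # the coin-flip rows carry the exact statistics
  cf_a <- cmp$tests[cmp$tests$parameter == "a" &
                    cmp$tests$test == "coin_flip" & cmp$tests$n_removed == 0, ]
  expect_equal(cf_a$statistic, 16.9)
  expect_lte(cf_a$p_value, 0.05)
  # correlation battery covers the pair plus four ratio-vs-value forms
  expect_equal(nrow(cmp$correlations), 12)
  expect_true(all(cmp$correlations$p_bonferroni >= cmp$correlations$p_value))
  expect_equal(nrow(cmp$regressions), 4)
  td <- tidy(cmp)
  expect_true(all(c("test", "correlation") %in% td$family))
  # identical seeds reproduce the whole report
  cmp2 <- compare_texts(ten_novels(), n_sims = 2000, n_perm = 5000, seed = 87)
  expect_equal(tidy(cmp), tidy(cmp2))
})

test_that("compare_texts on identical inputs finds no difference", {
  nov <- ten_novels()
  same <- nov
  same$gamma_l <- same$gamma_w
  same$sigma_l <- same$sigma_w
  same$a_l <- same$a_w
  cmp <- suppressWarnings(compare_texts(same, n_sims = 200, seed = 1))
  cf_rows <- cmp$tests[cmp$tests$test == "coin_flip", ]
  expect_true(all(cf_rows$p_value == 1))
  expect_true(all(cf_rows$statistic == 0))
  # undefined paired t on zero-variance differences degrades to NA
  expect_true(all(is.na(cmp$tests$statistic[cmp$tests$test == "paired_t"])))
  expect_true(all(abs(cmp$regressions$slope - 1) < 1e-10))
  expect_true(all(abs(cmp$regressions$intercept) < 1e-9))
})
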