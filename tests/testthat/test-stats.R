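test_that("robust regression recovers clean fits and bounds outlier influence", {
  x <- 1:30
  f <- robust_fit(x, 2 * x)
  expect_equal(unname(coef(f)[2]), 2, tolerance = 1e-8)
  expect_true(f$converged)

  # no outliers: matches ordinary least squares within 2% relative
  set.seed(10)
  y <- 1 + 2 * x + rnorm(30, 0, 1)
  fr <- robust_fit(x, y)
  ols <- coef(lm(y ~ x))
  expect_lt(abs(coef(fr)[2] - ols[2]) / abs(ols[2]), 0.02)

  # one gross outlier barely moves the robust slope, but drags OLS
  y_out <- y
  y_out[30] <- y_out[30] + 100
  slope_clean <- coef(fr)[2]
  slope_rob <- coef(robust_fit(x, y_out))[2]
  slope_ols <- coef(lm(y_out ~ x))[2]
  expect_lt(abs(slope_rob - slope_clean) / abs(slope_clean), 0.05)
  expect_gt(abs(slope_ols - slope_clean) / abs(slope_clean), 0.20)

  expect_error(robust_fit(cbind(x, x), y), "rank-deficient")
  expect_error(robust_fit(x[1:2], y[1:2]), "n > p")
  expect_error(robust_fit(x, rep(1, 30)), "constant")
})

test_that("robust regression agrees with an independent bisquare implementation", {
  skip_if_not_installed("MASS")
  set.seed(22)
  x <- rnorm(60)
  y <- 1 + 0.8 * x + rnorm(60, 0, 0.5)
  y[c(5, 40)] <- y[c(5, 40)] + 8
  ours <- coef(robust_fit(x, y))
  ref <- coef(MASS::rlm(y ~ x, psi = MASS::psi.bisquare, maxit = 100))
  expect_equal(unname(ours), unname(ref), tolerance = 0.02)
})

test_that("per-subject slope test detects built-in coupling and rejects degenerate input", {
  set.seed(5)
  dat <- do.call(rbind, lapply(1:12, function(s) {
    x <- rnorm(20)
    data.frame(subject = s, x = x, y = 0.5 * x + rnorm(20, 0, 0.3))
  }))
  res <- per_subject_slope_test(dat, side = "greater")
  expect_lt(res$p, 0.001)
  expect_equal(res$df, 11)
  expect_error(per_subject_slope_test(dat[dat$subject == 1, ]),
               "two subjects")
  expect_error(per_subject_slope_test(
    data.frame(subject = rep(1:2, each = 2), x = rnorm(4), y = rnorm(4))),
    "3 usable")
})

test_that("nonimpulsive rate counts delayed choices", {
  tr <- data.frame(
    condition = c("ecological", "ecological", "control", "control"),
    choice = c("nonimpulsive", "nonimpulsive", "nonimpulsive", "impulsive"))
  expect_equal(nonimpulsive_rate(tr), 0.75)
  expect_equal(nonimpulsive_rate(tr, "ecological"), 1.0)
  tr$choice <- "impulsive"
  expect_equal(nonimpulsive_rate(tr), 0.0)
  expect_error(nonimpulsive_rate(tr, "unknown-condition"), "no trials")
})

test_that("quantile binning is exact on constructed data and preserves the mean", {
  d <- data.frame(x = 1:18, y = 2 * (1:18))
  b <- bin_summary(d, n_bins = 9L)
  expect_equal(nrow(b), 9L)
  expect_equal(b$x_mean, seq(1.5, 17.5, by = 2))
  expect_equal(b$y_mean, 2 * seq(1.5, 17.5, by = 2))
  # weighted mean of bin means equals the overall mean
  expect_equal(sum(b$y_mean * 2) / 18, mean(d$y))
  b1 <- bin_summary(d, n_bins = 1L)
  expect_equal(b1$x_mean, mean(d$x)); expect_equal(b1$y_mean, mean(d$y))

  set.seed(3)
  big <- data.frame(x = runif(600), subject = rep(1:3, each = 200))
  big$y <- big$x
  bb <- bin_summary(big, subject = "subject", n_bins = 9L)
  expect_true(all(diff(bb$y_mean) > 0))
  expect_true(all(bb$n_subjects == 3L))
  expect_error(bin_summary(d[1:4, ], n_bins = 9L), "fewer observations")
})

test_that("the interaction GLM detects condition-specific coupling", {
  set.seed(7)
  n <- 19
  x <- rnorm(n)
  y_eco <- 1.0 * x + rnorm(n, 0, 0.2)
  y_ctl <- 0.0 * x + rnorm(n, 0, 0.2)
  res <- interaction_correlation_test(y_eco, y_ctl, x, side = "greater")
  expect_lt(res$p, 0.001)
  expect_equal(res$b3, 1, tolerance = 0.25)
  expect_equal(res$df, 2 * n - 4)
  # with covariates the df shrink accordingly
  res2 <- interaction_correlation_test(y_eco, y_ctl, x,
                                       covariates = data.frame(age = rnorm(n)))
  expect_equal(res2$df, 2 * n - 5)
  expect_error(interaction_correlation_test(y_eco, y_ctl, x,
                                            covariates = data.frame(bad = x)),
               "rank-deficient")
  expect_error(interaction_correlation_test(c(NA, y_eco[-1]), y_ctl, x),
               "missing condition")
})

test_that("the mixed ANOVA returns the split-plot interaction with correct dfs", {
  set.seed(8)
  n <- 15
  sm <- data.frame(
    subject = 1:(2 * n),
    group = rep(c("AD", "CTL"), each = n),
    eco = c(rnorm(n, 0.2, 0.1), rnorm(n, 0.6, 0.1)),
    ctl = rnorm(2 * n, 0.6, 0.1))
  long <- rbind(
    data.frame(subject = sm$subject, group = sm$group,
               condition = "ecological", rate = sm$eco),
    data.frame(subject = sm$subject, group = sm$group,
               condition = "control", rate = sm$ctl))
  res <- group_condition_interaction(long)
  expect_equal(res$df1, 1)
  expect_equal(res$df2, 28)
  expect_lt(res$p, 0.001)
  one_each <- long[long$subject %in% c(1, n + 1), ]
  expect_error(group_condition_interaction(one_each), "one subject per group")
  expect_error(group_condition_interaction(long[long$group == "AD", ]),
               "two groups")
})

test_that("the age-adjusted GLM isolates the group effect and drops constant age", {
  set.seed(9)
  n <- 30
  group <- rep(c("AD", "CTL"), each = n / 2)
  age <- rnorm(n, 70, 5)
  delta <- -0.4 * (group == "AD") + rnorm(n, 0, 0.1)
  res <- covariate_adjusted_group_test(delta, group, age)
  expect_lt(res$table["groupCTL", "p"], 0.001)
  expect_gt(res$table["age", "p"], 0.05)
  expect_warning(res2 <- covariate_adjusted_group_test(delta, group, rep(70, n)),
                 "constant")
  expect_equal(res2$dropped, "age")
  expect_true("groupCTL" %in% rownames(res2$table))
})

test_that("sidedness halves the p-value only on the correct side", {
  set.seed(11)
  x <- rnorm(25); y <- 0.6 * x + rnorm(25, 0, 0.5)
  two <- robust_slope_test(x, y, side = "two.sided")
  pos <- robust_slope_test(x, y, side = "greater")
  neg <- robust_slope_test(x, y, side = "less")
  expect_equal(pos$p, two$p / 2)
  expect_equal(neg$p, 1 - two$p / 2)
  expect_true(all(c(two$p, pos$p, neg$p) >= 0 & c(two$p, pos$p, neg$p) <= 1))
})
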