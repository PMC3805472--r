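test_that("the monetary transform maps the session range affinely onto [-10, 10]", {
  expect_equal(transform_monetary(c(0.5, 72)), c(-10, 10))
  expect_equal(transform_monetary(c(0.5, 36.25, 72)), c(-10, 0, 10))
  # midpoint of any range maps to 0
  expect_equal(transform_monetary(c(2, 5, 8))[2], 0)
  # order preserved
  a <- c(3, 1.5, 20, 7)
  expect_equal(order(transform_monetary(a)), order(a))
  expect_error(transform_monetary(c(4, 4, 4)), "degenerate")
})

test_that("hyperbolic discounting obeys its identities and monotonicity", {
  expect_equal(discounted_value(10, 0, 0.5), 10)
  expect_equal(discounted_value(8, 365, 1 / 365), 4)
  expect_equal(discounted_value(-5, 365, 1 / 365), -2.5)
  expect_error(discounted_value(5, -1, 0.1))
  expect_error(discounted_value(5, 10, -0.1))
  # strictly decreasing in D and k for R > 0, increasing for R < 0
  D <- c(1, 30, 365, 3650)
  for (k in c(0.001, 0.05, 1)) {
    expect_true(all(diff(discounted_value(7, D, k)) < 0))
    expect_true(all(diff(discounted_value(-7, D, k)) > 0))
  }
  ks <- c(0.001, 0.01, 0.1, 1)
  expect_true(all(diff(discounted_value(7, 365, ks)) < 0))
})

test_that("the softmax rule is complementary, symmetric and overflow-safe", {
  expect_equal(choice_probability(3, 3, 0.7), 0.5)
  expect_equal(choice_probability(10, 0, 10), 1 / (1 + exp(-1)))
  set.seed(4)
  Vi <- runif(50, -10, 10); Vd <- runif(50, -10, 10); b <- runif(50, 0.05, 20)
  expect_equal(choice_probability(Vi, Vd, b) + choice_probability(Vd, Vi, b),
               rep(1, 50))
  p <- choice_probability(-500, 500, 1)
  expect_gte(p, 0); expect_lt(p, 1e-100)
  expect_error(choice_probability(1, 2, 0))
})

test_that("the likelihood matches hand-computed values and is floored at the MLE", {
  eq <- vt(Vi = rep(0, 10), R_d = rep(0, 10), D = rep(365, 10),
           choice = rep(c("impulsive", "nonimpulsive"), 5))
  expect_equal(negative_log_likelihood(list(k = 0.02, beta = 1.3), eq),
               10 * log(2))
  one <- vt(10, 0, 365, "impulsive")
  # Pimp = plogis(1) = 0.7310586 at beta = 10, k large enough that Vd ~ 0
  expect_equal(negative_log_likelihood(list(k = 1e6, beta = 10), one),
               -log(plogis(1)), tolerance = 1e-8)
  expect_error(negative_log_likelihood(list(k = 0.1, beta = 1), eq[0, ]))

  tr <- make_recovery_trials(0.01, 2, seed = 31, sessions = 1L)
  fit <- fit_parameters(tr)
  nll_mle <- -fit$logLik
  for (k in c(0.001, 0.02, 0.3)) {
    for (b in c(0.5, 2, 8)) {
      expect_gte(negative_log_likelihood(list(k = k, beta = b), tr),
                 nll_mle - 1e-6)
    }
  }
  # the fitted model is at least as good as coin flipping
  expect_lte(nll_mle, nrow(tr) * log(2) + 1e-8)
})

test_that("the MLE is invariant to trial order and pools identical subjects", {
  tr <- make_recovery_trials(0.02, 1.5, seed = 8, sessions = 1L)
  f1 <- fit_parameters(tr)
  set.seed(99)
  f2 <- fit_parameters(tr[sample.int(nrow(tr)), ])
  expect_equal(f1$k, f2$k, tolerance = 1e-6)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-6)
  # group fit on two identical subjects has the same MLE as either alone
  fg <- fit_parameters(list(tr, tr), mode = "group")
  expect_equal(fg$k, f1$k, tolerance = 1e-4)
  expect_equal(fg$beta, f1$beta, tolerance = 1e-4)
  expect_equal(fg$n_trials, 2L * nrow(tr))
})

test_that("degenerate choice data sets the boundary flag without erroring", {
  tr <- make_recovery_trials(0.01, 2, seed = 12, sessions = 1L)
  tr$choice <- "nonimpulsive"
  f <- fit_parameters(tr)
  expect_true(f$boundary)
  expect_s3_class(f, "fit_result")
  # flat likelihood in k when all values are equal
  eq <- vt(Vi = rep(0, 20), R_d = rep(0, 20), D = rep(30, 20),
           choice = rep(c("impulsive", "nonimpulsive"), 10))
  expect_warning(feq <- fit_parameters(eq), "tied")
  expect_true(feq$boundary)
})

test_that("prediction scores hit the argmax limits and match a recount oracle", {
  agent <- agent_params(k = 0.01, beta = 2, delta_sim = 0)
  ratings <- simulate_ratings_and_richness(agent, seed = 3)
  sch <- generate_episodic_schedule("exp2", seed = 3)
  trv <- valued_trials(sch, ratings)
  Vd <- discounted_value(trv$R_d, trv$D, agent$k)
  untied <- trv$Vi != Vd
  # deterministic agent: choices follow the argmax
  det <- trv
  det$choice <- ifelse(trv$Vi > Vd, "impulsive", "nonimpulsive")
  expect_equal(prediction_score(agent, det[untied, ]), 100)
  anti <- det
  anti$choice <- ifelse(det$choice == "impulsive", "nonimpulsive", "impulsive")
  expect_equal(prediction_score(agent, anti[untied, ]), 0)

  # stochastic agent: score strictly inside (50, 100), equal to brute recount
  ch <- simulate_choices(agent, sch, ratings, seed = 11)
  tr <- valued_trials(sch, ratings, choices = ch)
  fit <- fit_parameters(tr)
  score <- prediction_score(fit, tr)
  expect_gt(score, 50); expect_lt(score, 100)
  vdf <- discounted_value(tr$R_d, tr$D, fit$k)
  keep <- tr$Vi != vdf
  manual <- 100 * sum((tr$choice == "impulsive") == (tr$Vi > vdf) & keep) / sum(keep)
  expect_equal(score, manual)
})

test_that("value differences match hand computation and the k = 0 limit", {
  tr <- vt(Vi = c(2, -3, 5), R_d = c(8, 6, 9), D = c(30, 365, 3650),
           choice = c("nonimpulsive", "impulsive", "nonimpulsive"))
  out <- value_difference(tr, list(k = 1 / 365))
  Vd <- c(8 / (1 + 30 / 365), 6 / 2, 9 / 11)
  expect_equal(out$vi_minus_vd, tr$Vi - Vd)
  expect_equal(out$chosen_minus_unchosen,
               c(Vd[1] - 2, -3 - Vd[2], Vd[3] - 5))
  out0 <- value_difference(tr, list(k = 0))
  expect_equal(out0$vi_minus_vd, tr$Vi - tr$R_d)
})

test_that("episodic valued trials join ratings by item and mode", {
  agent <- agent_params(delta_sim = 3)
  ratings <- simulate_ratings_and_richness(agent, seed = 6)
  sch <- generate_episodic_schedule("exp2", seed = 6)
  trv <- valued_trials(sch, ratings)
  i <- which(sch$subtype == "Obs/Sim")[1]
  rsim <- ratings[ratings$mode == "Sim", ]
  expect_equal(trv$R_d[trv$trial_index == sch$trial_index[i]],
               rsim$rating[rsim$item == sch$del_item[i]])
  expect_error(valued_trials(sch, ratings[ratings$item != sch$del_item[i], ]),
               sch$del_item[i], fixed = TRUE)
  expect_error(valued_trials(sch), "ratings")
})
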