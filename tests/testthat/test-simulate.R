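test_that("ratings respect scale bounds and the richness coupling", {
  # zero slope, zero noise: every rating equals the (rounded) baseline
  flat <- agent_params(b = 0, baseline_sd = 0, baseline_mean = 5,
                       tier_slope = 0, delta_sim = 0)
  r <- simulate_ratings_and_richness(flat, seed = 1)
  expect_true(all(r$rating == 5))

  # linear coupling: richness 0 vs 20 differ by b * 20 before clipping
  lin <- agent_params(b = 0.5, baseline_sd = 0, baseline_mean = 0,
                      tier_slope = 0, richness_mean = 10, delta_sim = 0)
  cat2 <- default_item_catalog()[c(1, 2), ]
  r2 <- simulate_ratings_and_richness(lin, cat2, seed = 1,
                                      richness = c(0L, 20L))
  obs <- r2[r2$mode == "Obs", ]
  expect_equal(obs$rating[2] - obs$rating[1], 10)

  # bounds hold even for extreme parameterizations
  wild <- agent_params(baseline_mean = 15, baseline_sd = 10, b = 1,
                       delta_sim = 12)
  for (seed in 1:5) {
    r3 <- simulate_ratings_and_richness(wild, seed = seed)
    expect_true(all(r3$rating >= -10 & r3$rating <= 10))
    rich <- r3$richness[r3$mode == "Sim"]
    expect_true(all(rich >= 0 & rich <= 20))
    expect_true(all(rich == round(rich)))
  }
})

test_that("presentation mode is value-neutral when the Sim deficit is zero", {
  a0 <- agent_params(delta_sim = 0)
  r <- simulate_ratings_and_richness(a0, seed = 4)
  expect_identical(r$rating[r$mode == "Obs"], r$rating[r$mode == "Sim"])
  a3 <- agent_params(delta_sim = 3, baseline_sd = 0, b = 0, tier_slope = 0,
                     baseline_mean = 2)
  r3 <- simulate_ratings_and_richness(a3, seed = 4)
  expect_true(all(r3$rating[r3$mode == "Obs"] -
                  r3$rating[r3$mode == "Sim"] == 3))
})

test_that("choices follow the softmax probabilities", {
  # near-deterministic agent always takes the better option
  agent <- agent_params(k = 1e-4, beta = 1e-6, delta_sim = 0)
  ratings <- simulate_ratings_and_richness(agent, seed = 2)
  sch <- generate_episodic_schedule("exp2", seed = 2)
  lat <- ratings[ratings$mode == "Obs", ]
  latmap <- setNames(lat$latent, lat$item)
  Vi <- unname(latmap[sch$imm_item])
  Vd <- discounted_value(unname(latmap[sch$del_item]), sch$delay_days, agent$k)
  ch <- simulate_choices(agent, sch, ratings, seed = 5)
  better_delayed <- Vd > Vi
  expect_true(all(ch$choice[order(ch$trial_index)][better_delayed] == "nonimpulsive"))

  # equal values: long-run impulsive rate is 1/2
  eq_agent <- agent_params(k = 0.01, beta = 2)
  n <- 10000L
  p <- rep(0.5, n)
  set.seed(77)
  rate <- mean(runif(n) < p)
  expect_lt(abs(rate - 0.5), 3 * sqrt(0.25 / n) + 1e-12)
  # via the package path: a schedule where Vi == Vd by construction
  expect_equal(unique(choice_probability(rep(1, 5), rep(1, 5), 2)), 0.5)

  # Monte-Carlo agreement between empirical frequencies and analytic Pimp
  agent2 <- agent_params(k = 0.01, beta = 2, delta_sim = 0)
  ratings2 <- simulate_ratings_and_richness(agent2, seed = 3)
  sch2 <- generate_episodic_schedule("exp2", seed = 3)
  reps <- 200L
  counts <- rep(0L, 72L)
  for (r in seq_len(reps)) {
    ch2 <- simulate_choices(agent2, sch2, ratings2, seed = 1000L + r)
    counts <- counts + (ch2$choice[order(ch2$trial_index)] == "impulsive")
  }
  p_hat <- counts / reps
  ch0 <- simulate_choices(agent2, sch2, ratings2, seed = 1)
  p_true <- ch0$p_impulsive[order(ch0$trial_index)]
  # per-trial deviations bounded by ~4 binomial SDs; strong overall match
  tol <- 4 * sqrt(pmax(p_true * (1 - p_true), 0.002) / reps)
  expect_true(mean(abs(p_hat - p_true) <= tol) > 0.98)
  expect_gt(cor(p_hat, p_true), 0.95)
})

test_that("neural generation follows the stated path structure", {
  d0 <- simulate_neural(n = 1000, beta1 = 0, beta2 = 0.7, seed = 1)
  expect_lt(abs(cor(d0$GM, d0$BOLD)), 0.1)
  d1 <- simulate_neural(n = 50, beta1 = 1, bold_noise_sd = 0, seed = 2)
  expect_equal(d1$BOLD, d1$GM)
  expect_error(simulate_neural(n = 10, bold_noise_sd = -1), "non-negative")
  carried <- simulate_neural(choice = 1:7, seed = 3)
  expect_equal(carried$CHOICE, 1:7)
})

test_that("cohorts are reproducible and phenotypes dissociate as constructed", {
  cfg <- cohort_config(groups = list(CTL = group_spec("CTL", 8),
                                     AD = group_spec("AD", 8),
                                     bvFTD = group_spec("bvFTD", 8)),
                       variant = "expB", episodic_sessions = 1L,
                       monetary_sessions = 0L, seed = 21)
  co <- simulate_cohort(cfg)
  co2 <- simulate_cohort(cfg)
  expect_identical(co$summary, co2$summary)
  sm <- co$summary
  expect_equal(as.integer(table(sm$group)[c("AD", "CTL", "bvFTD")]),
               c(8L, 8L, 8L))
  expect_true(all(sm$delta_sim[sm$group == "CTL"] == 0))
  expect_true(all(sm$delta_sim[sm$group == "AD"] > 0))
  # AD: ecological-specific impulsivity
  expect_lt(mean(sm$eco_rate[sm$group == "AD"]),
            mean(sm$ctl_rate[sm$group == "AD"]))
  # bvFTD: condition-general impulsivity (larger k)
  expect_lt(mean(sm$eco_rate[sm$group == "bvFTD"]),
            mean(sm$eco_rate[sm$group == "CTL"]))
  expect_lt(mean(sm$ctl_rate[sm$group == "bvFTD"]),
            mean(sm$ctl_rate[sm$group == "CTL"]))
})

test_that("cohort configuration is validated", {
  expect_error(group_spec("healthy", 0), ">= 1")
  expect_error(cohort_config(groups = list()), "at least one group")
  expect_error(cohort_config(groups = list(group_spec("healthy", 5))), "named")
  expect_error(cohort_config(neural = list(bold_noise_sd = -0.1)),
               "non-negative")
})
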