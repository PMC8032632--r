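test_that("generation is deterministic given configuration and seed", {
  cfg <- tiny_scenario(n = 30, seed = 99)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
  w <- simulate_cohort(cfg)
  o1 <- simulate_outcomes(w, cfg)
  o2 <- simulate_outcomes(w, cfg)
  expect_identical(as.data.frame(o1), as.data.frame(o2))
  # beat level too
  bcfg <- scenario_config(n_workers = 2, seed = 4, fidelity = "beat_level")
  s1 <- simulate_beat_cohort(bcfg)
  s2 <- simulate_beat_cohort(bcfg)
  expect_identical(s1$streams, s2$streams)
  expect_identical(s1$ground_truth, s2$ground_truth)
})

test_that("degenerate scenario puts every attribute exactly at its mean", {
  cfg <- degenerate_scenario(n = 1)
  w <- simulate_cohort(cfg)
  expect_equal(w$age, 44)
  expect_equal(w$vo2max, 32)
  expect_equal(w$body_mass, 80)
  expect_equal(w$hr_min_true, 60)
  expect_equal(as.character(w$occupation), "manufacturing")
  expect_equal(w$n_days, 3L)
  o <- simulate_outcomes(w, cfg)
  expect_equal(o$hrr_mean, 30)
  expect_equal(o$hrr_max_1min, 57)
  expect_equal(o$prop_above_30, 0.47)
})

test_that("null effect with zero noise collapses outcomes to the intercept", {
  cfg <- tiny_scenario(
    n = 25, seed = 3,
    covariate_offsets = zero_offsets,
    hrr_mean = list(mean = 30, sd = 7.4, slope = 0, resid_sd = 0),
    hrr_max = list(mean = 57, sd = 10.5, slope = 0, resid_sd = 0),
    composition = list(p_median = 0.47, p_q1 = 0.23, p_q3 = 0.70,
                       delta_pct = 0, resid_sd = 0))
  o <- simulate_outcomes(simulate_cohort(cfg), cfg)
  expect_equal(o$hrr_mean, rep(30, 25))
  expect_equal(o$hrr_max_1min, rep(57, 25))
  expect_equal(o$prop_above_30, rep(0.47, 25))
})

test_that("one cohort at full size lands near the demographic targets", {
  cfg <- default_scenario(n_workers = 497, seed = 12)
  w <- simulate_cohort(cfg)
  expect_lt(abs(mean(w$age) - 44), 1.5)
  expect_lt(abs(mean(w$vo2max) - 32), 1.3)
  expect_lt(abs(mean(w$sex == "female") - 0.41), 0.07)
  expect_lt(cor(w$age, w$vo2max), -0.1)   # fitness declines with age
  expect_true(all(w$age >= 18 & w$age <= 68))
  expect_true(all(w$vo2max > 0))
  expect_true(all(w$n_days %in% 1:4))
})

test_that("invalid configurations are rejected before any stage runs", {
  expect_error(scenario_config(n_workers = 0), "n_workers")
  expect_error(scenario_config(age = list(mean = 44, sd = -1, min = 18,
                                          max = 68)), "sd")
  expect_error(scenario_config(days_probs = c(`1` = 0.5, `2` = 0.6,
                                              `3` = 0, `4` = 0)), "sum to 1")
  expect_error(scenario_config(p_female = 1.2), "proportions")
  expect_error(scenario_config(age_fitness_cor = 1), "age_fitness_cor")
})

test_that("artifact injection is the identity at zero rates and logs inserts", {
  cfg <- scenario_config(n_workers = 1, seed = 8)
  w <- simulate_cohort(cfg)
  w$hrr_mean <- 30; w$hrr_max_1min <- 57; w$prop_above_30 <- 0.47
  sim <- simulate_ibi_stream(w, config = cfg)
  r0 <- inject_artifacts(sim$ibi, list(), seed = 1)
  expect_identical(r0$series, sim$ibi)
  expect_equal(nrow(r0$log), 0)
  r <- inject_artifacts(sim$ibi, list(out_of_range = 0.01, ectopic = 0.005),
                        seed = 1)
  n <- nrow(sim$ibi)
  n_oor <- sum(r$log$type == "out_of_range")
  n_ect <- sum(r$log$type == "ectopic")
  expect_lt(abs(n_oor - 0.01 * n) / (0.01 * n), 0.35)
  expect_lt(abs(n_ect - 0.005 * n) / (0.005 * n), 0.35)
  # injected out-of-range beats really are out of range
  hr <- 60000 / r$series$ibi_ms[r$log$index[r$log$type == "out_of_range"]]
  expect_true(all(hr < 36 | hr > 200))
})

test_that("the calibrated composition slope survives the analysis round trip", {
  # zero-noise cohort: fitting the ilr outcome and back-transforming must
  # reproduce the configured absolute change almost exactly
  cfg <- tiny_scenario(
    n = 60, seed = 21, covariate_offsets = zero_offsets,
    hrr_mean = list(mean = 30, sd = 7.4, slope = -0.32, resid_sd = 0),
    hrr_max = list(mean = 57, sd = 10.5, slope = -0.35, resid_sd = 0),
    composition = list(p_median = 0.47, p_q1 = 0.23, p_q3 = 0.70,
                       delta_pct = -1.8, resid_sd = 0))
  ac <- simulate_analysis_cohort(cfg)
  est <- suppressWarnings(fit_model(ac$rows, "ilr_z"))
  bt <- backtransform_delta_pct(est)
  expect_equal(bt$delta_pct, -1.8, tolerance = 0.05)
})
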