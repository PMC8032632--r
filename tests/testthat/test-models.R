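zero_noise_cfg <- function(n = 80, seed = 1, offsets = NULL, ...) {
  args <- list(
    n_workers = n, seed = seed,
    hrr_mean = list(mean = 30, sd = 7.4, slope = -0.32, resid_sd = 0),
    hrr_max = list(mean = 57, sd = 10.5, slope = -0.35, resid_sd = 0),
    composition = list(p_median = 0.47, p_q1 = 0.23, p_q3 = 0.70,
                       delta_pct = -1.8, resid_sd = 0), ...)
  if (!is.null(offsets)) args$covariate_offsets <- offsets
  do.call(scenario_config, args)
}

test_that("zero-noise data return the injected slope to numerical precision", {
  ac <- simulate_analysis_cohort(zero_noise_cfg(offsets = zero_offsets))
  expect_equal(suppressWarnings(fit_model(ac$rows, "hrr_mean"))$estimate, -0.32,
               tolerance = 1e-10)
  expect_equal(suppressWarnings(fit_model(ac$rows, "hrr_max_1min"))$estimate, -0.35,
               tolerance = 1e-10)
  # with covariate offsets present, the adjusted model is still exact
  ac2 <- simulate_analysis_cohort(zero_noise_cfg(seed = 2))
  est <- suppressWarnings(fit_model(ac2$rows, "hrr_mean", adjusted = TRUE))
  expect_equal(est$estimate, -0.32, tolerance = 1e-10)
  expect_true(est$ci_lo <= est$estimate & est$estimate <= est$ci_hi)
})

test_that("slope is equivariant under rescaling of the exposure", {
  ac <- simulate_analysis_cohort(tiny_scenario(n = 120, seed = 6))
  e1 <- fit_model(ac$rows, "hrr_mean")
  rows2 <- ac$rows
  rows2$vo2max_rel <- rows2$vo2max_rel * 2
  e2 <- fit_model(rows2, "hrr_mean")
  expect_equal(e2$estimate, e1$estimate / 2, tolerance = 1e-12)
})

test_that("unadjusted and adjusted estimates coincide without covariate effects", {
  ac <- simulate_analysis_cohort(zero_noise_cfg(offsets = zero_offsets,
                                                seed = 5))
  u <- suppressWarnings(fit_model(ac$rows, "hrr_mean", adjusted = FALSE))
  a <- suppressWarnings(fit_model(ac$rows, "hrr_mean", adjusted = TRUE))
  expect_equal(u$estimate, a$estimate, tolerance = 1e-9)
})

test_that("permuting the outcome centres the slope on zero", {
  ac <- simulate_analysis_cohort(tiny_scenario(n = 150, seed = 8))
  set.seed(13)
  sl <- replicate(40, {
    rows <- ac$rows
    rows$hrr_mean <- sample(rows$hrr_mean)
    fit_model(rows, "hrr_mean")$estimate
  })
  expect_lt(abs(mean(sl)), 3 * sd(sl) / sqrt(length(sl)) + 1e-9)
})

test_that("the product-term coefficient is invariant to centring", {
  ac <- simulate_analysis_cohort(tiny_scenario(n = 150, seed = 9))
  it <- interaction_test(ac$rows, "hrr_mean")
  raw <- lm(hrr_mean ~ vo2max_rel * age + sex + self_rated_health +
              shift_nonday + medication + occupation, data = ac$rows)
  expect_equal(it$estimate, unname(coef(raw)["vo2max_rel:age"]),
               tolerance = 1e-9)
})

test_that("a monotone age profile of slopes is detected by the product term", {
  hits <- vapply(1:12, function(s) {
    cfg <- age_interaction_scenario(
      n_workers = 497, seed = s,
      slopes_mean = c(-0.05, -0.25, -0.45, -0.65),
      slopes_max = c(-0.2, -0.3, -0.45, -0.55),
      delta_pct = c(-0.5, -1.2, -2.2, -3.0))
    ac <- simulate_analysis_cohort(cfg)
    interaction_test(ac$rows, "hrr_mean")$p < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.5)
})

test_that("under no interaction the product-term p-values look uniform", {
  ps <- vapply(1:30, function(s) {
    ac <- simulate_analysis_cohort(default_scenario(n_workers = 250, seed = s))
    interaction_test(ac$rows, "hrr_mean")$p
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("stratified estimates partition the sample and flag small strata", {
  ac <- simulate_analysis_cohort(tiny_scenario(n = 200, seed = 10))
  st <- suppressWarnings(stratify(ac$rows, by = "age_quartiles",
                                  outcome = "hrr_mean"))
  expect_equal(sum(st$n), nrow(ac$rows))
  st2 <- suppressWarnings(stratify(ac$rows, by = "occupation",
                                   outcome = "hrr_mean"))
  expect_equal(sum(st2$n), nrow(ac$rows))
  expect_true(any(st2$unstable))   # cleaning/transport are small groups
  # pinned bands are honoured
  st3 <- suppressWarnings(stratify(ac$rows, by = "age_quartiles",
                                   outcome = "hrr_mean",
                                   breaks = c(-Inf, 37, 45, 51, Inf),
                                   labels = c("<=37", "38-45", "46-51",
                                              ">=52")))
  expect_setequal(st3$stratum, c("<=37", "38-45", "46-51", ">=52"))
})

test_that("degenerate factors in a stratum are dropped with a warning", {
  ac <- simulate_analysis_cohort(tiny_scenario(n = 120, seed = 11))
  rows <- ac$rows
  rows$occupation <- factor("manufacturing",
                            levels = levels(rows$occupation))
  expect_warning(fit_model(rows, "hrr_mean", adjusted = TRUE), "degenerate")
})

test_that("flat composition models back-transform to zero change", {
  cfg <- zero_noise_cfg(offsets = zero_offsets, seed = 14)
  cfg$composition$delta_pct <- 0
  ac <- simulate_analysis_cohort(cfg)
  est <- suppressWarnings(fit_model(ac$rows, "ilr_z"))
  bt <- backtransform_delta_pct(est)
  expect_equal(bt$delta_pct, 0, tolerance = 1e-8)
  expect_equal(bt$ci_lo, bt$ci_hi, tolerance = 1e-6)
})

test_that("too few complete rows is an explicit error", {
  ac <- simulate_analysis_cohort(tiny_scenario(n = 40, seed = 15))
  expect_error(fit_model(ac$rows[1:10, ], "hrr_mean"), "complete rows")
})
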