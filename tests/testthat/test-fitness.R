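test_that("steady-state rule is a strict 5 beats/min criterion", {
  expect_true(steady_state_reached(130, 133))
  expect_false(steady_state_reached(130, 136))
  expect_false(steady_state_reached(130, 135))   # strict "less than 5"
  expect_false(steady_state_reached(NA, 130))
})

test_that("power adjustment targets max(60% of estimated max, 120)", {
  expect_equal(power_adjustment_needed(100, hr_max_tanaka(40)), 120)
  expect_null(power_adjustment_needed(115, hr_max_tanaka(40)))
  expect_equal(power_adjustment_needed(109, hr_max_tanaka(20)), 120)
  # an older heart would be driven by the 60% arm if it exceeded 120
  expect_equal(power_adjustment_needed(100, 210), 126)
})

make_test <- function(power_w, hr_ss, sex = "male", age = 25, mass = 80) {
  # readings converge and then sit at hr_ss from minute 5
  list(power_w = power_w, cadence = 60,
       hr_readings = c(hr_ss - 20, hr_ss - 10, hr_ss - 4, hr_ss - 1,
                       hr_ss, hr_ss),
       sex = sex, age = age, body_mass = mass)
}

test_that("nomogram estimate matches a hand lookup of the shipped tables", {
  # male, 100 W (= 612 kpm/min), steady state 130, age 25 (factor 1.0):
  # oxygen cost interpolates 600->1.5 and 750->1.8 to 1.524 L/min; the
  # pulse line gives (130 - 61) / 134 = 0.514925 of maximum
  r <- estimate_vo2max(make_test(100, 130))
  expect_equal(r$vo2max_abs, 1.524 / ((130 - 61) / 134), tolerance = 1e-6)
  expect_equal(r$vo2max_rel, 1000 * r$vo2max_abs / 80)
  expect_true(r$steady_state)
})

test_that("estimates are monotone in heart rate and power", {
  v_low <- estimate_vo2max(make_test(100, 125))$vo2max_abs
  v_high <- estimate_vo2max(make_test(100, 145))$vo2max_abs
  expect_gt(v_low, v_high)   # same power, higher pulse -> lower fitness
  p_low <- estimate_vo2max(make_test(80, 130))$vo2max_abs
  p_high <- estimate_vo2max(make_test(120, 130))$vo2max_abs
  expect_gt(p_high, p_low)
})

test_that("age correction is the identity at the reference age and separable", {
  base <- estimate_vo2max(make_test(100, 130, age = 25))$vo2max_abs
  at40 <- estimate_vo2max(make_test(100, 130, age = 40))$vo2max_abs
  at50 <- estimate_vo2max(make_test(100, 130, age = 50))$vo2max_abs
  expect_equal(at40 / base, 0.83, tolerance = 1e-9)
  expect_equal(at40 / at50, 0.83 / 0.75, tolerance = 1e-9)
})

test_that("out-of-range steady-state pulses refuse to extrapolate", {
  expect_error(estimate_vo2max(make_test(100, 175)),
               class = "workhrr_range_error")
  expect_error(estimate_vo2max(make_test(100, 112)),
               class = "workhrr_range_error")
})

test_that("a session that never steadies by minute 10 yields no estimate", {
  t <- list(power_w = 100, cadence = 60,
            hr_readings = seq(100, 190, by = 10), sex = "male", age = 30,
            body_mass = 80)
  r <- estimate_vo2max(t)
  expect_false(r$steady_state)
  expect_true(is.na(r$vo2max_abs))
  # a session with strong cardiovascular drift behaves the same
  w <- tibble::tibble(vo2max = 35, body_mass = 80, sex = "male", age = 30)
  slow <- simulate_test_session(w, protocol = list(hr_drift = 6))
  expect_false(slow$result$steady_state)
})

test_that("noiseless sessions recover true fitness within 5% across the range", {
  cfg <- scenario_config(n_workers = 50, seed = 5)
  w <- simulate_cohort(cfg)
  err <- vapply(seq_len(nrow(w)), function(i) {
    r <- simulate_test_session(w[i, ])$result
    if (is.na(r$vo2max_rel)) return(NA_real_)
    abs(r$vo2max_rel - w$vo2max[i]) / w$vo2max[i]
  }, numeric(1))
  expect_true(all(!is.na(err)))
  expect_lt(max(err), 0.05)
})

test_that("the adjustment rule fires for fit workers started too low", {
  w <- tibble::tibble(vo2max = 48, body_mass = 75, sex = "male", age = 30)
  s <- simulate_test_session(w, protocol = list(initial_power_w = 60))
  expect_true(s$result$power_adjusted)
  expect_lt(s$test$hr_readings[1], 110)
  expect_gte(max(s$test$hr_readings), 118)
  expect_lt(abs(s$result$vo2max_rel - 48) / 48, 0.05)
})

test_that("a pulse outside the table at the lowest workload propagates as missing", {
  w <- tibble::tibble(vo2max = 12, body_mass = 100, sex = "male", age = 25)
  s <- simulate_test_session(w)
  expect_true(s$result$out_of_range)
  expect_true(is.na(s$result$vo2max_rel))
})

test_that("the eligibility screen excludes on any listed criterion", {
  w <- tibble::tibble(worker_id = "w")
  expect_true(fitness_eligible(w))
  expect_false(fitness_eligible(w, systolic = 165))
  expect_false(fitness_eligible(w, diastolic = 100))
  bad <- fitness_eligible(w, angina = TRUE, fever = TRUE)
  expect_false(bad)
  expect_equal(length(attr(bad, "reasons")), 2)
})
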