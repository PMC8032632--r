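test_that("range filter applies the strict 36/200 bpm rule", {
  s <- make_series(c(800, 2000, 800, 300, 60000 / 36, 250, 800))
  r <- filter_hr_range(s)
  # 2000 ms = 30 bpm discarded; 250 ms = 240 bpm discarded
  expect_equal(r$series$ibi_ms, c(800, 800, 300, 60000 / 36, 800))
  expect_equal(r$report$n_removed_range, 2)
  # boundary beats at exactly 36 and 200 bpm are retained
  b <- filter_hr_range(make_series(c(60000 / 36, 300)))
  expect_equal(nrow(b$series), 2)
  # empty input
  e <- filter_hr_range(make_series(numeric(0)))
  expect_equal(nrow(e$series), 0)
  expect_equal(e$report$n_removed_range, 0)
})

test_that("neighbour filter removes isolated outliers but keeps ramps", {
  s <- make_series(c(800, 800, 1000, 800, 800))
  r <- filter_neighbor_deviation(s)
  expect_equal(r$series$ibi_ms, c(800, 800, 800, 800))
  expect_equal(r$report$n_removed_neighbor, 1)
  # constant sequence untouched
  c0 <- filter_neighbor_deviation(make_series(rep(900, 20)))
  expect_equal(nrow(c0$series), 20)
  # monotone ramp with steps below 15% untouched
  ramp <- make_series(800 * 1.14^(0:10))
  expect_equal(nrow(filter_neighbor_deviation(ramp)$series), 11)
  # a step change survives the both-sided rule but not the one-sided one
  step <- make_series(c(rep(1000, 5), rep(700, 5)))
  expect_equal(nrow(filter_neighbor_deviation(step)$series), 10)
  expect_lt(nrow(filter_neighbor_deviation(step, mode = "one_sided")$series), 10)
  # series shorter than 2 returned unchanged
  one <- make_series(1000)
  expect_identical(filter_neighbor_deviation(one)$series, one)
})

test_that("beat-error rule removes bad epochs and invalidates bad measurements", {
  # 60 one-second beats in minute one, 40 of them flagged (67% > 50%)
  flags <- c(rep(1L, 40), rep(0L, 20), rep(0L, 60))
  s <- make_series(rep(1000, 120), error_flag = flags)
  r <- exclude_by_beat_error(s)
  expect_equal(r$report$epochs_excluded, 1)
  expect_true(all(r$series$time_s >= 60))
  expect_true(r$report$measurement_valid)
  # clean epoch retained in full
  clean <- exclude_by_beat_error(make_series(rep(1000, 60)))
  expect_equal(nrow(clean$series), 60)
  # 55% flagged overall: whole measurement invalid
  s2 <- make_series(rep(1000, 100), error_flag = c(rep(1L, 55), rep(0L, 45)))
  r2 <- exclude_by_beat_error(s2)
  expect_false(r2$report$measurement_valid)
  expect_equal(nrow(r2$series), 0)
})

test_that("each filter is idempotent and only ever removes beats", {
  set.seed(7)
  for (i in 1:20) {
    ibi <- 1000 * exp(cumsum(rnorm(300, 0, 0.02)))
    idx <- sample(300, 5)
    ibi[idx] <- ibi[idx] * sample(c(0.5, 1.6), 5, TRUE)
    s <- make_series(ibi, error_flag = rbinom(300, 1, 0.05))
    for (f in list(function(x) filter_hr_range(x)$series,
                   function(x) filter_neighbor_deviation(x)$series,
                   function(x) exclude_by_beat_error(x)$series)) {
      once <- f(s)
      expect_identical(f(once), once)
      expect_true(all(once$time_s %in% s$time_s))  # subset, no fabrication
    }
  }
})

test_that("4 Hz resampling is linear interpolation of instantaneous HR", {
  # constant 1000 ms beats -> every sample exactly 60 bpm
  r <- resample_4hz(make_series(rep(1000, 100)))
  expect_true(all(r$hr_bpm == 60))
  expect_equal(diff(r$time_s), rep(0.25, nrow(r) - 1))
  # two anchors 10 s apart at 60 and 80 bpm: midpoint sample is 70
  s2 <- tibble::tibble(time_s = c(10, 20), ibi_ms = c(1000, 750),
                       error_flag = 0L)
  r2 <- resample_4hz(s2)
  expect_equal(r2$hr_bpm[r2$time_s == 15], 70)
  # affine HR signals are reproduced exactly at grid times
  tt <- sort(runif(60, 0, 120))
  hr <- 60 + 0.2 * tt
  s3 <- tibble::tibble(time_s = tt, ibi_ms = 60000 / hr, error_flag = 0L)
  r3 <- resample_4hz(s3, max_gap_s = 1e6)
  expect_equal(r3$hr_bpm, 60 + 0.2 * r3$time_s, tolerance = 1e-12)
  # fewer than 2 beats -> fully masked
  expect_equal(nrow(resample_4hz(make_series(1000))), 0)
})

test_that("samples inside long gaps are masked instead of interpolated", {
  s <- make_series(c(rep(1000, 10), 30000, rep(1000, 10)))
  r <- resample_4hz(s, max_gap_s = 5)
  gap_start <- s$time_s[10]
  gap_end <- s$time_s[11]
  in_gap <- r$time_s > gap_start & r$time_s < gap_end
  expect_true(all(!r$valid[in_gap]))
  expect_true(all(r$valid[!in_gap]))
})

test_that("diary splitting uses half-open intervals and flags overlap", {
  diary <- tibble::tibble(period = c("sleep", "work"),
                          start_s = c(0, 28800), end_s = c(28800, 57600))
  hr <- tibble::tibble(time_s = c(28800.25, 57600, 100, 60000),
                       hr_bpm = 70, valid = TRUE)
  out <- split_by_diary(hr, diary)
  expect_equal(out$period, c("work", "uncovered", "sleep", "uncovered"))
  # full coverage leaves no uncovered samples
  full <- tibble::tibble(period = c("sleep", "work", "leisure"),
                         start_s = c(0, 28800, 57600),
                         end_s = c(28800, 57600, 86400))
  grid <- tibble::tibble(time_s = seq(0, 86399.75, by = 0.25),
                         hr_bpm = 70, valid = TRUE)
  expect_true(all(split_by_diary(grid, full)$period != "uncovered"))
  # overlapping intervals are a validation error naming the intervals
  bad <- tibble::tibble(period = c("work", "leisure"),
                        start_s = c(0, 100), end_s = c(200, 300))
  expect_error(split_by_diary(hr, bad), "overlap")
})

test_that("the cleaning chain reports counts that add up", {
  set.seed(11)
  ibi <- rep(1000, 500)
  ibi[c(50, 150)] <- 2500       # out of range
  ibi[c(250)] <- 1400           # isolated ectopic
  s <- make_series(ibi, error_flag = 0L)
  r <- clean_ibi(s)
  rep_ <- r$report
  expect_equal(rep_$n_in - rep_$n_removed_range - rep_$n_removed_neighbor -
                 rep_$n_removed_error, rep_$n_retained)
  expect_equal(rep_$n_removed_range, 2)
  expect_equal(rep_$n_removed_neighbor, 1)
})
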