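#' Discard beats outside the physiological heart-rate range
#'
#' Removes beats whose instantaneous heart rate (`60000 / ibi_ms`) is below
#' 36 or above 200 beats/min. The rule is a strict inequality, so beats at
#' exactly the boundaries are retained; a small numeric tolerance guards the
#' boundary against floating-point round-off.
#'
#' @param series Tibble with `time_s` (strictly increasing), `ibi_ms` (> 0)
#'   and `error_flag`.
#' @param hr_low,hr_high Range bounds, beats/min.
#' @return List `series` (filtered, order preserved) and `report` (named
#'   list of counts).
#' @export
filter_hr_range <- function(series, hr_low = 36, hr_high = 200) {
  n <- nrow(series)
  if (n == 0) {
    return(list(series = series,
                report = list(n_in = 0L, n_removed_range = 0L)))
  }
  hr <- 60000 / series$ibi_ms
  eps <- 1e-9
  keep <- hr >= hr_low - eps & hr <= hr_high + eps
  list(series = series[keep, ],
       report = list(n_in = n, n_removed_range = sum(!keep)))
}

#' Discard isolated beats deviating from their neighbours
#'
#' Single-pass neighbour-deviation filter: an interior beat is discarded iff
#' its relative difference to *both* adjacent beats (each neighbour as
#' reference) exceeds `tol`; first and last beats are compared to their
#' single neighbour. This removes isolated ectopic beats while retaining
#' genuine ramps and step changes, where a beat deviates from only one side.
#' The one-sided variant (`mode = "one_sided"`) discards on either
#' violation.
#'
#' @param series Tibble with `time_s`, `ibi_ms`, `error_flag`. Series
#'   shorter than 2 beats are returned unchanged.
#' @param tol Relative deviation threshold (default 0.15, i.e. 15%).
#' @param mode `"both_sides"` (default, isolated-outlier semantics) or
#'   `"one_sided"`.
#' @return List `series` and `report` (`n_removed_neighbor` count).
#' @export
filter_neighbor_deviation <- function(series, tol = 0.15,
                                      mode = c("both_sides", "one_sided")) {
  mode <- match.arg(mode)
  n <- nrow(series)
  if (n < 2) {
    return(list(series = series,
                report = list(n_in = n, n_removed_neighbor = 0L)))
  }
  x <- series$ibi_ms
  dev_prev <- c(NA, abs(diff(x)) / head(x, -1))        # vs earlier neighbour
  dev_next <- c(abs(diff(x)) / tail(x, -1), NA)        # vs later neighbour
  viol_prev <- !is.na(dev_prev) & dev_prev > tol
  viol_next <- !is.na(dev_next) & dev_next > tol
  drop <- if (mode == "both_sides") {
    # ends have one neighbour: that single comparison decides
    ifelse(is.na(dev_prev), viol_next,
           ifelse(is.na(dev_next), viol_prev, viol_prev & viol_next))
  } else {
    viol_prev | viol_next
  }
  list(series = series[!drop, ],
       report = list(n_in = n, n_removed_neighbor = sum(drop)))
}

#' Exclude epochs (and whole measurements) with excessive beat-error rates
#'
#' Splits the series into fixed epochs and removes all beats of any epoch in
#' which the fraction of device-flagged error beats exceeds `max_rate`. If
#' the flagged fraction over the whole measurement exceeds `max_rate`, the
#' entire series is invalidated (all beats removed,
#' `measurement_valid = FALSE`).
#'
#' @param series Tibble with `time_s`, `ibi_ms`, `error_flag` (0/1).
#' @param epoch_s Epoch length in seconds (default 60).
#' @param max_rate Maximum tolerated flagged fraction (default 0.5).
#' @return List `series` and `report` (`n_removed_error`, `epochs_excluded`,
#'   `measurement_valid`).
#' @export
exclude_by_beat_error <- function(series, epoch_s = 60, max_rate = 0.5) {
  n <- nrow(series)
  if (n == 0) {
    return(list(series = series,
                report = list(n_in = 0L, n_removed_error = 0L,
                              epochs_excluded = 0L, measurement_valid = TRUE)))
  }
  overall <- mean(series$error_flag > 0)
  if (overall > max_rate) {
    return(list(series = series[0, ],
                report = list(n_in = n, n_removed_error = n,
                              epochs_excluded = NA_integer_,
                              measurement_valid = FALSE)))
  }
  epoch <- floor(series$time_s / epoch_s)
  rate <- tapply(series$error_flag > 0, epoch, mean)
  bad <- names(rate)[rate > max_rate]
  drop <- as.character(epoch) %in% bad
  list(series = series[!drop, ],
       report = list(n_in = n, n_removed_error = sum(drop),
                     epochs_excluded = length(bad), measurement_valid = TRUE))
}

#' Full inter-beat-interval cleaning chain
#'
#' Applies the three discard rules in order — physiological range, neighbour
#' deviation, beat-error epochs — and merges their reports. Each filter is
#' idempotent and only ever removes beats, so the output is a subset of the
#' input in the original order.
#'
#' @inheritParams filter_neighbor_deviation
#' @inheritParams exclude_by_beat_error
#' @return List `series` (cleaned) and `report`: per-rule counts, retained
#'   count and `fraction_retained` (`discarded + retained = input`).
#' @export
clean_ibi <- function(series, tol = 0.15, mode = "both_sides",
                      epoch_s = 60, max_rate = 0.5) {
  n_in <- nrow(series)
  s1 <- filter_hr_range(series)
  s2 <- filter_neighbor_deviation(s1$series, tol = tol, mode = mode)
  s3 <- exclude_by_beat_error(s2$series, epoch_s = epoch_s,
                              max_rate = max_rate)
  n_out <- nrow(s3$series)
  report <- list(n_in = n_in,
                 n_removed_range = s1$report$n_removed_range,
                 n_removed_neighbor = s2$report$n_removed_neighbor,
                 n_removed_error = s3$report$n_removed_error,
                 epochs_excluded = s3$report$epochs_excluded,
                 measurement_valid = s3$report$measurement_valid,
                 n_retained = n_out,
                 fraction_retained = if (n_in > 0) n_out / n_in else NA_real_)
  list(series = s3$series, report = report)
}

#' Resample a cleaned beat stream to a 4 Hz heart-rate signal
#'
#' Anchors the instantaneous heart rate (`60000 / ibi_ms`) at the beat times
#' and linearly interpolates onto a regular 0.25 s grid. Interpolation is
#' performed on heart rate, not on interval length. Grid samples falling
#' inside an inter-beat gap longer than `max_gap_s` are masked invalid
#' rather than interpolated, so long dropouts do not manufacture data.
#'
#' @param series Cleaned beat tibble (`time_s`, `ibi_ms`).
#' @param max_gap_s Longest gap (s) across which interpolation is trusted.
#' @param fs Sampling frequency, Hz.
#' @return Tibble `time_s`, `hr_bpm`, `valid`; fewer than two beats yield a
#'   zero-row (fully masked) series.
#' @export
resample_4hz <- function(series, max_gap_s = 10, fs = 4) {
  if (nrow(series) < 2) {
    return(tibble(time_s = numeric(0), hr_bpm = numeric(0),
                  valid = logical(0)))
  }
  t <- series$time_s
  hr <- 60000 / series$ibi_ms
  step <- 1 / fs
  grid <- seq(ceiling(t[1] / step) * step, floor(t[length(t)] / step) * step,
              by = step)
  if (!length(grid)) {
    return(tibble(time_s = numeric(0), hr_bpm = numeric(0),
                  valid = logical(0)))
  }
  y <- approx(t, hr, xout = grid, ties = "ordered")$y
  left <- findInterval(grid, t)
  left <- pmin(pmax(left, 1L), length(t) - 1L)
  gap <- t[left + 1L] - t[left]
  valid <- gap <= max_gap_s | grid %in% t
  tibble(time_s = grid, hr_bpm = y, valid = valid)
}

#' Assign 4 Hz samples to diary periods
#'
#' Labels every sample with the diary period whose half-open interval
#' `[start_s, end_s)` contains it, or `"uncovered"` if none does. Intervals
#' must not overlap within a day.
#'
#' @param hr Tibble from [resample_4hz()].
#' @param diary Tibble with `period`, `start_s`, `end_s`.
#' @return `hr` with an added `period` column.
#' @export
split_by_diary <- function(hr, diary) {
  validate_day_plan(diary)
  o <- order(diary$start_s)
  diary <- diary[o, ]
  idx <- findInterval(hr$time_s, diary$start_s)
  period <- rep("uncovered", nrow(hr))
  inside <- idx >= 1 & idx <= nrow(diary)
  hit <- inside & hr$time_s < diary$end_s[pmax(idx, 1L)]
  period[hit] <- diary$period[idx[hit]]
  hr$period <- period
  hr
}
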