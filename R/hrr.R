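#' Minimum heart rate over a 10-beat moving window
#'
#' The resting anchor of the heart-rate-reserve calculation: the minimum,
#' over all windows of 10 consecutive retained beats in the whole
#' measurement, of the window-mean instantaneous heart rate. Averaging over
#' ten beats keeps a single aberrant beat from defining the minimum. The
#' window mean is taken on instantaneous heart rate (60000/IBI), not on
#' interval length; the two differ only at second order.
#'
#' @param ibi_ms Cleaned inter-beat intervals (ms) over the whole
#'   measurement, in time order (all measured days pooled).
#' @param window Number of beats per window (default 10).
#' @return Minimum window-mean heart rate (bpm), or `NA` with a warning if
#'   fewer than `window` beats are available (measurement invalid).
#' @export
hr_min_10beat <- function(ibi_ms, window = 10L) {
  n <- length(ibi_ms)
  if (n < window) {
    warning("fewer than ", window, " beats; minimum heart rate undefined.")
    return(NA_real_)
  }
  hr <- 60000 / ibi_ms
  cs <- cumsum(c(0, hr))
  means <- (cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]) / window
  min(means)
}

#' Age-predicted maximal heart rate (Tanaka)
#'
#' `208 - 0.7 * age` beats/min.
#'
#' @param age Age in years (> 0).
#' @return Predicted maximal heart rate, bpm.
#' @export
#' @examples
#' hr_max_tanaka(40)  # 180
hr_max_tanaka <- function(age) {
  if (any(age <= 0)) stop("`age` must be positive.", call. = FALSE)
  208 - 0.7 * age
}

#' Percentage of heart rate reserve (Karvonen)
#'
#' `100 * (hr - hr_min) / (hr_max - hr_min)`, the working heart rate
#' expressed relative to the individual span between minimum and maximal
#' heart rate. Values are clamped to \[0, 100\] — a working heart rate below
#' the measured minimum or above the age-predicted maximum is truncated —
#' and the clamp counts are attached as attributes `n_clamped_low` /
#' `n_clamped_high` for quality-control reporting.
#'
#' @param hr Heart rate(s), bpm.
#' @param hr_min,hr_max Individual minimum and maximal heart rate;
#'   `hr_max > hr_min > 0` required.
#' @return %HRR vector in \[0, 100\].
#' @export
#' @examples
#' percent_hrr(120, hr_min = 60, hr_max = 180)  # 50
percent_hrr <- function(hr, hr_min, hr_max) {
  if (!(hr_max > hr_min && hr_min > 0)) {
    stop("need hr_max > hr_min > 0.", call. = FALSE)
  }
  raw <- 100 * (hr - hr_min) / (hr_max - hr_min)
  out <- pmin(pmax(raw, 0), 100)
  attr(out, "n_clamped_low") <- sum(raw < 0)
  attr(out, "n_clamped_high") <- sum(raw > 100)
  out
}

#' Maximum workload level sustained for a minimum cumulative duration
#'
#' The 1-minute exceedance outcome: the largest %HRR level at or above which
#' the worker spent at least `min_duration_s` of (not necessarily
#' contiguous) valid work time. With samples at `fs` Hz this is the value at
#' rank `ceiling(min_duration_s * fs)` of the samples sorted in decreasing
#' order, which coincides with a brute-force scan over candidate levels.
#'
#' @param pct Valid work-period %HRR samples.
#' @param min_duration_s Minimum cumulative duration, seconds (default 60).
#' @param fs Sampling frequency, Hz (default 4).
#' @return The exceedance level, or `NA` if fewer than
#'   `ceiling(min_duration_s * fs)` valid samples exist.
#' @export
exceedance_max <- function(pct, min_duration_s = 60, fs = 4) {
  k <- ceiling(min_duration_s * fs)
  pct <- pct[is.finite(pct)]
  if (length(pct) < k) return(NA_real_)
  sort(pct, decreasing = TRUE)[k]
}

#' Work-time composition above and below the workload cut-off
#'
#' Splits valid work time into the seconds spent at or above the cut-off
#' ("at or above" — a sample exactly at the cut-off counts as above) and
#' strictly below it. The two parts sum to the total valid work time
#' exactly.
#'
#' @param pct Valid work-period %HRR samples.
#' @param cutoff Workload cut-off, %HRR (default 30).
#' @param fs Sampling frequency, Hz.
#' @return Named numeric vector `c(t_above =, t_below =)`, seconds.
#' @export
time_composition <- function(pct, cutoff = 30, fs = 4) {
  pct <- pct[is.finite(pct)]
  c(t_above = sum(pct >= cutoff) / fs, t_below = sum(pct < cutoff) / fs)
}

#' Valid-day and valid-worker rules
#'
#' A measured day is valid if it contains at least 4 hours of work-period
#' heart-rate data, or at least 75% of that worker's average diary work
#' hours across measured days. A worker is valid if at least one day is.
#'
#' @param work_valid_h Hours of valid work-period heart-rate data per
#'   measured day.
#' @param diary_work_h Diary (scheduled) work hours per measured day.
#' @return List `day_valid` (logical per day), `worker_valid`, and `reason`
#'   when the worker is invalid.
#' @export
day_validity <- function(work_valid_h, diary_work_h) {
  if (length(diary_work_h) == 0 || all(diary_work_h <= 0)) {
    return(list(day_valid = rep(FALSE, length(work_valid_h)),
                worker_valid = FALSE, reason = "no diary work periods"))
  }
  avg_work <- mean(diary_work_h)
  day_valid <- work_valid_h >= 4 | work_valid_h >= 0.75 * avg_work
  list(day_valid = day_valid, worker_valid = any(day_valid),
       reason = if (any(day_valid)) NA_character_ else "no valid day")
}

#' Summarise a worker's pooled work-period workload
#'
#' Pools the valid work-period %HRR samples of all valid days
#' (sample-weighted: every valid 4 Hz sample counts equally) and computes
#' the three outcomes: mean %HRR, the 1-minute exceedance level and the
#' proportion of work time at or above the cut-off.
#'
#' @param pct Pooled valid work-period %HRR samples of the worker's valid
#'   days.
#' @param worker_id Identifier carried into the output.
#' @param n_valid_days Number of valid days pooled.
#' @param cutoff,min_duration_s,fs Outcome parameters; see
#'   [time_composition()] and [exceedance_max()].
#' @param valid Worker-level validity flag; if `FALSE` outcomes are `NA`.
#' @return One-row tibble: `worker_id`, `hrr_mean`, `hrr_max_1min`,
#'   `prop_above_30`, `work_time_valid_h`, `n_valid_days`, `valid`.
#' @export
summarize_worker <- function(pct, worker_id, n_valid_days = 1L, cutoff = 30,
                             min_duration_s = 60, fs = 4, valid = TRUE) {
  if (!valid || length(pct) == 0) {
    return(tibble(worker_id = worker_id, hrr_mean = NA_real_,
                  hrr_max_1min = NA_real_, prop_above_30 = NA_real_,
                  work_time_valid_h = 0, n_valid_days = 0L, valid = FALSE))
  }
  comp <- time_composition(pct, cutoff = cutoff, fs = fs)
  total_s <- sum(comp)
  tibble(worker_id = worker_id,
         hrr_mean = mean(pct),
         hrr_max_1min = exceedance_max(pct, min_duration_s, fs),
         prop_above_30 = unname(comp["t_above"] / total_s),
         work_time_valid_h = total_s / 3600,
         n_valid_days = as.integer(n_valid_days),
         valid = TRUE)
}

#' Run the full beat-to-outcome pipeline for a set of workers
#'
#' For every worker: clean each day's beat stream (range, neighbour and
#' beat-error rules), pool the cleaned beats of all days to estimate the
#' 10-beat minimum heart rate, resample each day to 4 Hz, split by the
#' diary, convert valid work samples to %HRR using the Tanaka age-predicted
#' maximum, apply the valid-day rules and summarise.
#'
#' @param streams Beat tibble with `worker_id`, `day`, `time_s`, `ibi_ms`,
#'   `error_flag` (e.g. from [simulate_beat_cohort()]).
#' @param diary Diary tibble with `worker_id`, `day`, `period`, `start_s`,
#'   `end_s`.
#' @param workers Tibble with `worker_id` and `age`.
#' @param max_gap_s,tol,epoch_s,max_rate,cutoff,min_duration_s,fs Pipeline
#'   parameters; see the individual stage functions.
#' @return List `summaries` (tibble, one row per worker) and `qc` (per
#'   worker-day cleaning reports).
#' @export
workload_from_streams <- function(streams, diary, workers, max_gap_s = 10,
                                  tol = 0.15, epoch_s = 60, max_rate = 0.5,
                                  cutoff = 30, min_duration_s = 60, fs = 4) {
  summaries <- list()
  qc <- list()
  for (wid in unique(streams$worker_id)) {
    w_beats <- streams[streams$worker_id == wid, ]
    w_diary <- diary[diary$worker_id == wid, ]
    age <- workers$age[match(wid, workers$worker_id)]
    days <- sort(unique(w_beats$day))
    cleaned <- list()
    work_pct_by_day <- vector("list", length(days))
    work_valid_h <- numeric(length(days))
    diary_work_h <- numeric(length(days))
    for (i in seq_along(days)) {
      d <- days[i]
      s <- clean_ibi(w_beats[w_beats$day == d,
                             c("time_s", "ibi_ms", "error_flag")],
                     tol = tol, epoch_s = epoch_s, max_rate = max_rate)
      qc[[paste(wid, d, sep = "_")]] <- s$report
      cleaned[[i]] <- s$series
      d_diary <- w_diary[w_diary$day == d, ]
      diary_work_h[i] <-
        sum(with(d_diary[d_diary$period == "work", ], end_s - start_s)) / 3600
      hr <- resample_4hz(s$series, max_gap_s = max_gap_s, fs = fs)
      if (nrow(hr) == 0) next
      hr <- split_by_diary(hr, d_diary)
      work <- hr[hr$period == "work" & hr$valid, ]
      work_valid_h[i] <- nrow(work) / fs / 3600
      work_pct_by_day[[i]] <- work$hr_bpm
    }
    all_beats <- dplyr::bind_rows(cleaned)
    hr_min <- if (nrow(all_beats) >= 10) {
      hr_min_10beat(all_beats$ibi_ms)
    } else NA_real_
    val <- day_validity(work_valid_h, diary_work_h)
    if (!val$worker_valid || is.na(hr_min)) {
      summaries[[wid]] <- summarize_worker(numeric(0), wid, valid = FALSE)
      next
    }
    hr_max <- hr_max_tanaka(age)
    pooled_hr <- unlist(work_pct_by_day[val$day_valid], use.names = FALSE)
    pct <- percent_hrr(pooled_hr, hr_min, hr_max)
    summaries[[wid]] <- summarize_worker(pct, wid,
                                         n_valid_days = sum(val$day_valid),
                                         cutoff = cutoff,
                                         min_duration_s = min_duration_s,
                                         fs = fs)
  }
  list(summaries = dplyr::bind_rows(summaries), qc = qc)
}
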