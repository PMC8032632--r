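#' Default diary structure of a measured day
#'
#' Sleep 00:00-07:00, work 08:00-15:30 (7.5 h) and leisure in between and
#' after, expressed in seconds from the start of the day. The sleep block is
#' where the simulated heart rate sits at the worker's true minimum, so the
#' 10-beat minimum-HR estimator can recover it.
#'
#' @return A tibble with columns `period`, `start_s`, `end_s` covering the
#'   whole day without overlap.
#' @export
default_day_plan <- function() {
  tibble(period = c("sleep", "leisure", "work", "leisure"),
         start_s = c(0, 25200, 28800, 55800),
         end_s = c(25200, 28800, 55800, 86400))
}

validate_day_plan <- function(day_plan) {
  stopifnot(all(c("period", "start_s", "end_s") %in% names(day_plan)))
  if (any(day_plan$end_s <= day_plan$start_s)) {
    stop("day plan intervals must have end_s > start_s.", call. = FALSE)
  }
  o <- order(day_plan$start_s)
  s <- day_plan$start_s[o]
  e <- day_plan$end_s[o]
  bad <- which(s[-1] < e[-length(e)])
  if (length(bad)) {
    stop(sprintf("day plan intervals overlap: [%g, %g) and [%g, %g).",
                 s[bad[1]], e[bad[1]], s[bad[1] + 1], e[bad[1] + 1]),
         call. = FALSE)
  }
  invisible(day_plan)
}

# Piecewise-constant work intensity profile (in %HRR) achieving a target
# (mean, 1-min exceedance level, proportion >= cutoff). The peak bout lasts
# `bout_s` seconds at the exceedance level; one block sits between the
# cutoff and the peak, one below the cutoff. Targets outside the feasible
# set are projected onto it; the achieved values are returned.
plan_work_profile <- function(gt_mean, gt_max, gt_prop, work_s,
                              cutoff = 30, bout_s = 120) {
  m <- gt_mean
  M <- min(max(gt_max, cutoff + 2), 98)
  q_min <- bout_s / work_s + 0.002
  q <- min(max(gt_prop, q_min), 0.995)
  t_bout <- bout_s
  t_a <- q * work_s - t_bout
  t_b <- (1 - q) * work_s
  a_lo <- cutoff + 0.01
  a_hi <- M - 0.01
  a <- min(max((cutoff + M) / 2, a_lo), a_hi)
  b <- if (t_b > 0) (m * work_s - M * t_bout - a * t_a) / t_b else 0
  if (b < 0 || b > cutoff - 0.5) {
    b <- min(max(b, 0), cutoff - 0.5)
    a <- (m * work_s - M * t_bout - b * t_b) / t_a
    a <- min(max(a, a_lo), a_hi)
  }
  m_ach <- (M * t_bout + a * t_a + b * t_b) / work_s
  segs <- tibble(pct = c(b, a, M, a, b),
                 dur_s = c(t_b / 2, t_a / 2, t_bout, t_a / 2, t_b / 2))
  segs <- segs[segs$dur_s > 0, ]
  list(segments = segs,
       achieved = c(hrr_mean = m_ach, hrr_max = M, prop_above = q))
}

# Beats for one constant-HR stretch: inter-beat intervals 60000/hr ms with
# multiplicative lognormal jitter (unit mean), cut at the segment end.
gen_segment_beats <- function(t0, t1, hr, jitter_sd) {
  dur <- t1 - t0
  if (dur <= 0 || hr <= 0) {
    return(tibble(time_s = numeric(0), ibi_ms = numeric(0)))
  }
  ibi0 <- 60000 / hr
  n <- ceiling(dur / (ibi0 / 1000) * (1 + 5 * jitter_sd) + 10)
  j <- if (jitter_sd > 0) {
    exp(rnorm(n, -jitter_sd^2 / 2, jitter_sd))
  } else {
    rep(1, n)
  }
  ibi <- ibi0 * j
  tt <- t0 + cumsum(ibi) / 1000
  keep <- tt <= t1
  tibble(time_s = tt[keep], ibi_ms = ibi[keep])
}

#' Simulate a beat-level inter-beat-interval stream for one worker-day
#'
#' Emits a full day of beats whose instantaneous heart rate follows a
#' piecewise-constant target profile: the sleep block sits at the worker's
#' true minimum heart rate, leisure at a low intensity, and the work window
#' is shaped so that the derived workload outcomes (mean %HRR, 1-minute
#' exceedance level, proportion of work time at/above the cut-off) equal the
#' worker's ground-truth values. Inter-beat intervals are `60000 / HR(t)` ms
#' with multiplicative lognormal beat-to-beat jitter.
#'
#' @param worker One-row tibble with at least `age`, `hr_min_true` and the
#'   ground-truth outcomes `hrr_mean`, `hrr_max_1min`, `prop_above_30`.
#' @param day_plan Diary tibble (`period`, `start_s`, `end_s`), non-
#'   overlapping; see [default_day_plan()].
#' @param config An [scenario_config()]; `config$beat` controls jitter, the
#'   leisure intensity and the peak-bout duration.
#' @param cutoff Workload cut-off, %HRR.
#' @return List with `ibi` (tibble `time_s`, `ibi_ms`, `error_flag`),
#'   `diary` (the validated day plan) and `achieved` (the profile's exact
#'   work-period mean/max/proportion after feasibility projection).
#' @export
simulate_ibi_stream <- function(worker, day_plan = default_day_plan(),
                                config = scenario_config(), cutoff = 30) {
  validate_day_plan(day_plan)
  hr_max <- hr_max_tanaka(worker$age)
  hr_min <- worker$hr_min_true
  reserve <- hr_max - hr_min
  pct_to_hr <- function(pct) hr_min + pct / 100 * reserve

  work <- day_plan[day_plan$period == "work", ]
  segments <- list()
  achieved <- NULL
  for (i in seq_len(nrow(day_plan))) {
    p <- day_plan$period[i]
    t0 <- day_plan$start_s[i]
    t1 <- day_plan$end_s[i]
    if (p == "sleep") {
      segments[[length(segments) + 1]] <- tibble(t0 = t0, t1 = t1, hr = hr_min)
    } else if (p == "leisure") {
      segments[[length(segments) + 1]] <-
        tibble(t0 = t0, t1 = t1, hr = pct_to_hr(config$beat$leisure_pct))
    } else if (p == "work") {
      prof <- plan_work_profile(worker$hrr_mean, worker$hrr_max_1min,
                                worker$prop_above_30, work_s = t1 - t0,
                                cutoff = cutoff, bout_s = config$beat$bout_s)
      achieved <- prof$achieved
      starts <- t0 + cumsum(c(0, head(prof$segments$dur_s, -1)))
      segments[[length(segments) + 1]] <-
        tibble(t0 = starts, t1 = starts + prof$segments$dur_s,
               hr = pct_to_hr(prof$segments$pct))
    } else {
      # non-wear: no beats emitted
    }
  }
  segments <- dplyr::bind_rows(segments)
  beats <- dplyr::bind_rows(lapply(seq_len(nrow(segments)), function(i) {
    gen_segment_beats(segments$t0[i], segments$t1[i], segments$hr[i],
                      config$beat$jitter_sd)
  }))
  beats <- beats[order(beats$time_s), ]
  beats$error_flag <- 0L
  list(ibi = as_tibble(beats), diary = day_plan, achieved = achieved)
}

#' Simulate a beat-level cohort with streams, diaries and ground truth
#'
#' Draws a cohort and its metric-level outcome values, then emits for every
#' worker `n_days` beat-level days whose work profile reproduces those
#' values. The recorded ground truth is the *achieved* profile value after
#' projection onto the feasible set (rarely different from the drawn value),
#' which is what the full pipeline should recover.
#'
#' @param config An [scenario_config()] (any fidelity; beat options under
#'   `config$beat` apply).
#' @param n_workers Optional override of `config$n_workers` (beat-level runs
#'   are usually much smaller than metric-level ones).
#' @return List with `workers`, `streams` (tibble of beats with `worker_id`
#'   and `day`), `diary` (tibble of labelled intervals per worker-day) and
#'   `ground_truth` (per-worker achieved outcomes).
#' @export
simulate_beat_cohort <- function(config, n_workers = NULL) {
  if (!is.null(n_workers)) config$n_workers <- n_workers
  validate_scenario(config)
  workers <- simulate_cohort(config)
  outcomes <- simulate_outcomes(workers, config)
  streams <- list()
  diaries <- list()
  gt <- list()
  for (w in seq_len(nrow(workers))) {
    row <- dplyr::bind_cols(workers[w, ],
                            outcomes[w, c("hrr_mean", "hrr_max_1min",
                                          "prop_above_30")])
    for (d in seq_len(workers$n_days[w])) {
      set.seed(derive_seed(config$seed, 100L + w * 5L + d))
      sim <- simulate_ibi_stream(row, config = config)
      art <- config$beat$artifact
      if (any(unlist(art) > 0)) {
        inj <- inject_artifacts(sim$ibi, art,
                                seed = derive_seed(config$seed, 10000L + w * 5L + d))
        sim$ibi <- inj$series
      }
      streams[[length(streams) + 1]] <-
        dplyr::bind_cols(tibble(worker_id = workers$worker_id[w], day = d),
                         sim$ibi)
      diaries[[length(diaries) + 1]] <-
        dplyr::bind_cols(tibble(worker_id = workers$worker_id[w], day = d),
                         sim$diary)
    }
    gt[[w]] <- tibble(worker_id = workers$worker_id[w],
                      hrr_mean = sim$achieved["hrr_mean"],
                      hrr_max_1min = sim$achieved["hrr_max"],
                      prop_above_30 = sim$achieved["prop_above"])
  }
  list(workers = workers,
       streams = dplyr::bind_rows(streams),
       diary = dplyr::bind_rows(diaries),
       ground_truth = dplyr::bind_rows(gt))
}

#' Inject measurement artifacts into a beat stream
#'
#' Contaminates a clean inter-beat-interval series with the artifact classes
#' the quality-control rules are designed to remove: physiologically
#' out-of-range beats (instantaneous HR below 36 or above 200 bpm), isolated
#' ectopic beats (deviating > 15% from both neighbours), runs of
#' device-flagged error beats, and non-wear gaps (beats deleted). Returns
#' the contaminated series plus an injection log for recall checks.
#'
#' @param series Tibble with `time_s`, `ibi_ms`, `error_flag`.
#' @param rates List with elements `out_of_range`, `ectopic`,
#'   `flagged_runs`, `nonwear` — per-beat probabilities in \[0, 1\] (for
#'   `flagged_runs` the rate of run starts; for `nonwear` the expected
#'   fraction of time removed).
#' @param seed Optional seed for reproducible injection.
#' @param run_length Beats per flagged-error run (default 90, enough to push
#'   a 60 s epoch above the 50% error-rate threshold).
#' @return List `series` (contaminated) and `log` (tibble `type`, `index`,
#'   `time_s` of every injected artifact, indices referring to the output
#'   series).
#' @export
inject_artifacts <- function(series, rates = list(), seed = NULL,
                             run_length = 90L) {
  r <- utils::modifyList(list(out_of_range = 0, ectopic = 0,
                              flagged_runs = 0, nonwear = 0), rates)
  if (any(unlist(r) < 0) || any(unlist(r) > 1)) {
    stop("artifact rates must be in [0, 1].", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  out <- series
  log <- list()
  n <- nrow(out)
  if (n == 0 || all(unlist(r) == 0)) {
    return(list(series = out, log = tibble(type = character(0),
                                           index = integer(0),
                                           time_s = numeric(0))))
  }
  # non-wear first (removes beats; later indices refer to the final series)
  if (r$nonwear > 0) {
    span <- diff(range(out$time_s))
    gap_len <- r$nonwear * span
    g0 <- runif(1, min(out$time_s), max(out$time_s) - gap_len)
    drop <- out$time_s >= g0 & out$time_s < g0 + gap_len
    out <- out[!drop, ]
    log[[length(log) + 1]] <- tibble(type = "nonwear", index = NA_integer_,
                                     time_s = g0)
    n <- nrow(out)
  }
  interior <- 2:(n - 1)
  if (r$ectopic > 0 && n > 2) {
    k <- rbinom(1, length(interior), r$ectopic)
    idx <- sort(sample(interior, k))
    fac <- sample(c(0.7, 1.35), length(idx), TRUE)
    out$ibi_ms[idx] <- out$ibi_ms[idx] * fac
    log[[length(log) + 1]] <- tibble(type = "ectopic", index = idx,
                                     time_s = out$time_s[idx])
  }
  if (r$out_of_range > 0 && n > 2) {
    k <- rbinom(1, length(interior), r$out_of_range)
    idx <- sort(sample(interior, k))
    low <- runif(length(idx)) < 0.5
    hr_bad <- ifelse(low, runif(length(idx), 20, 34),
                     runif(length(idx), 205, 240))
    out$ibi_ms[idx] <- 60000 / hr_bad
    log[[length(log) + 1]] <- tibble(type = "out_of_range", index = idx,
                                     time_s = out$time_s[idx])
  }
  if (r$flagged_runs > 0 && n > run_length) {
    k <- max(1L, rbinom(1, n, r$flagged_runs))
    starts <- sort(sample(seq_len(n - run_length), k))
    for (s in starts) {
      out$error_flag[s:(s + run_length - 1L)] <- 1L
    }
    log[[length(log) + 1]] <- tibble(type = "flagged_run", index = starts,
                                     time_s = out$time_s[starts])
  }
  log <- if (length(log)) dplyr::bind_rows(log) else {
    tibble(type = character(0), index = integer(0), time_s = numeric(0))
  }
  list(series = out, log = log)
}
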