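# Build an IBI series tibble from interval lengths (ms); times cumulative.
make_series <- function(ibi_ms, start_s = 0, error_flag = 0L) {
  tibble::tibble(time_s = start_s + cumsum(ibi_ms) / 1000,
                 ibi_ms = ibi_ms,
                 error_flag = rep_len(error_flag, length(ibi_ms)))
}

# Independent brute-force oracle for the 1-min exceedance outcome: scan all
# observed values as candidate levels and keep the largest with enough
# cumulative time at or above it.
brute_exceedance <- function(x, k) {
  if (length(x) < k) return(NA_real_)
  cand <- unique(x)
  ok <- vapply(cand, function(l) sum(x >= l) >= k, logical(1))
  max(cand[ok])
}

# Brute-force oracle for the 10-beat minimum heart rate.
brute_hr_min <- function(ibi_ms, window = 10L) {
  hr <- 60000 / ibi_ms
  n <- length(hr)
  min(vapply(seq_len(n - window + 1),
             function(i) mean(hr[i:(i + window - 1)]), numeric(1)))
}

# A small scenario for fast tests.
tiny_scenario <- function(n = 40, seed = 1, ...) {
  scenario_config(n_workers = n, seed = seed, ...)
}

# Scenario with every configurable SD and offset at zero: all workers land
# exactly on the configured means.
degenerate_scenario <- function(n = 1, seed = 1) {
  scenario_config(
    n_workers = n, seed = seed,
    age = list(mean = 44, sd = 0, min = 18, max = 68),
    vo2max = list(mean = 32, sd = 0, min = 10, max = 60),
    age_fitness_cor = 0,
    p_female = 0,
    occupation_probs = c(administration = 0, cleaning = 0,
                         manufacturing = 1, transportation = 0),
    shift_probs = c(fixed_day = 1, night_varying = 0, other = 0),
    srh_probs = c(`1` = 0, `2` = 1, `3` = 0, `4` = 0, `5` = 0),
    p_medication = 0,
    steps = list(meanlog = log(1000), sdlog = 0),
    body_mass = list(mean = 80, sd = 0, min = 45, max = 140),
    hr_min_true = list(mean = 60, sd = 0, min = 40, max = 85),
    work_hours_per_day = list(mean = 7, sd = 0, min = 2, max = 12),
    days_probs = c(`1` = 0, `2` = 0, `3` = 1, `4` = 0),
    hrr_mean = list(mean = 30, sd = 7.4, slope = -0.32, resid_sd = 0),
    hrr_max = list(mean = 57, sd = 10.5, slope = -0.35, resid_sd = 0),
    composition = list(p_median = 0.47, p_q1 = 0.23, p_q3 = 0.70,
                       delta_pct = -1.8, resid_sd = 0))
}

zero_offsets <- list(sex_female = 0,
                     occupation = c(administration = 0, cleaning = 0,
                                    manufacturing = 0, transportation = 0),
                     shift_nonday = 0, medication = 0)
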