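# cache for the nomogram data files
.fitness_env <- new.env(parent = emptyenv())

#' Åstrand–Ryhming nomogram tables
#'
#' Loads the versioned data files shipped with the package: the sex-specific
#' nomogram pulse-rate parameters, the oxygen-cost ladder of cycle-ergometer
#' work, and the age-correction factors. See the file headers under
#' `inst/extdata/` for provenance notes.
#'
#' @return List with tibbles `nomogram`, `vo2_cost`, `age_correction`.
#' @export
ar_nomogram <- function() {
  if (is.null(.fitness_env$tables)) {
    rd <- function(f) {
      as_tibble(read.csv(system.file("extdata", f, package = "workhrr"),
                         comment.char = "#", stringsAsFactors = FALSE))
    }
    .fitness_env$tables <- list(
      nomogram = rd("astrand_ryhming_nomogram.csv"),
      vo2_cost = rd("astrand_vo2_cost.csv"),
      age_correction = rd("astrand_age_correction.csv"))
  }
  .fitness_env$tables
}

watts_to_kpm <- function(power_w) power_w * 6.12

# oxygen cost (L/min) of cycling at a workload in kpm/min
vo2_cost_at <- function(kpm) {
  tab <- ar_nomogram()$vo2_cost
  approx(tab$workload_kpm, tab$vo2_l_min, xout = kpm, rule = 2)$y
}

age_correction_at <- function(age) {
  tab <- ar_nomogram()$age_correction
  approx(tab$age, tab$factor, xout = age, rule = 2)$y
}

# fraction of VO2max at a given steady-state pulse, from the nomogram line
# through (hr_at_half_max, 0.5) and (hr_max_ref, 1.0)
nomogram_pct_max <- function(hr_ss, sex) {
  tab <- ar_nomogram()$nomogram
  p <- tab[tab$sex == as.character(sex), ]
  if (nrow(p) != 1) stop("unknown sex for nomogram lookup.", call. = FALSE)
  0.5 + 0.5 * (hr_ss - p$hr_at_half_max) / (p$hr_max_ref - p$hr_at_half_max)
}

nomogram_hr_range <- function(sex) {
  tab <- ar_nomogram()$nomogram
  p <- tab[tab$sex == as.character(sex), ]
  c(p$hr_valid_low, p$hr_valid_high)
}

#' Steady-state rule of the submaximal test
#'
#' Steady state is reached when the heart rate changes by strictly less
#' than 5 beats/min between two consecutive minute readings (the protocol
#' checks minutes 5 to 6 first and keeps cycling until the 10-minute cap).
#'
#' @param hr_a,hr_b Consecutive minute readings, bpm (`NA` if missing).
#' @return `TRUE` iff both readings are present and `|hr_b - hr_a| < 5`.
#' @export
#' @examples
#' steady_state_reached(130, 133)  # TRUE
#' steady_state_reached(130, 135)  # FALSE: the rule is strict
steady_state_reached <- function(hr_a, hr_b) {
  if (is.na(hr_a) || is.na(hr_b)) return(FALSE)
  abs(hr_b - hr_a) < 5
}

#' Power-adjustment rule after the first minute
#'
#' If the heart rate registered after the first minute is below 110
#' beats/min, the power output is increased until the registered heart rate
#' is at or above 60% of the estimated maximal heart rate, or at least 120
#' beats/min, whichever is larger.
#'
#' @param hr_min1 Heart rate after the first minute, bpm.
#' @param est_hr_max Estimated maximal heart rate (from [hr_max_tanaka()]).
#' @return Target heart rate (bpm) if an adjustment is needed, else `NULL`.
#' @export
#' @examples
#' power_adjustment_needed(100, hr_max_tanaka(40))  # 120
#' power_adjustment_needed(115, hr_max_tanaka(40))  # NULL
power_adjustment_needed <- function(hr_min1, est_hr_max) {
  if (hr_min1 >= 110) return(NULL)
  max(0.6 * est_hr_max, 120)
}

#' Estimate maximal oxygen uptake from a submaximal ergometer test
#'
#' Applies the Åstrand–Ryhming nomogram to the combination of power output
#' and steady-state heart rate: the oxygen cost of the workload is divided
#' by the nomogram fraction of maximum at the steady-state pulse and
#' multiplied by the published age-correction factor. The steady-state
#' heart rate is the mean of the two consecutive minute readings that first
#' satisfy [steady_state_reached()] (minute 6 at the earliest, minute 10 at
#' the latest). No extrapolation is performed outside the tabulated pulse
#' range; an out-of-range steady-state pulse raises a condition of class
#' `workhrr_range_error`.
#'
#' @param test List describing the test: `power_w`, `cadence`,
#'   `hr_readings` (per-minute bpm, up to 10), `sex` (`"female"`/`"male"`),
#'   `age` (years), `body_mass` (kg), optionally `power_adjusted`.
#' @return One-row tibble: `vo2max_abs` (L/min), `vo2max_rel`
#'   (mlO2/min/kg), `steady_state`, `power_adjusted`, `termination_minute`.
#'   If no steady state is reached within 10 minutes the estimates are `NA`
#'   and `steady_state` is `FALSE`.
#' @export
estimate_vo2max <- function(test) {
  stopifnot(all(c("power_w", "hr_readings", "sex", "age", "body_mass")
                %in% names(test)))
  if (test$power_w <= 0) stop("`power_w` must be positive.", call. = FALSE)
  hr <- test$hr_readings
  hr <- hr[seq_len(min(length(hr), 10L))]
  adj <- isTRUE(test$power_adjusted)
  term <- NA_integer_
  for (m in 6:length(hr)) {
    if (length(hr) < 6) break
    if (steady_state_reached(hr[m - 1], hr[m])) {
      term <- m
      break
    }
  }
  if (is.na(term)) {
    return(tibble(vo2max_abs = NA_real_, vo2max_rel = NA_real_,
                  steady_state = FALSE, power_adjusted = adj,
                  termination_minute = min(length(hr), 10L)))
  }
  hr_ss <- mean(hr[c(term - 1, term)])
  rng <- nomogram_hr_range(test$sex)
  if (hr_ss < rng[1] || hr_ss > rng[2]) {
    stop(errorCondition(
      sprintf("steady-state heart rate %.1f outside tabulated range [%g, %g]",
              hr_ss, rng[1], rng[2]),
      class = c("workhrr_range_error", "error")))
  }
  vo2w <- vo2_cost_at(watts_to_kpm(test$power_w))
  pct <- nomogram_pct_max(hr_ss, test$sex)
  abs_raw <- vo2w / pct
  abs_corr <- abs_raw * age_correction_at(test$age)
  tibble(vo2max_abs = abs_corr,
         vo2max_rel = 1000 * abs_corr / test$body_mass,
         steady_state = TRUE, power_adjusted = adj,
         termination_minute = term)
}

#' Simulate a submaximal test session for a synthetic worker
#'
#' Harness exercising the full test protocol against a worker with known
#' fitness: the steady-state heart rate implied by the worker's true VO2max
#' at the set power is obtained by inverting the same nomogram relation
#' used forward, per-minute readings converge exponentially toward it (and
#' are rounded to whole beats, as a pulse oximeter reports), the
#' power-adjustment rule fires when the first-minute reading is below 110,
#' and the 10-minute cap applies. A steady-state pulse outside the
#' tabulated range propagates as a missing estimate.
#'
#' @param worker One-row tibble with `vo2max` (mlO2/min/kg, ground truth),
#'   `body_mass`, `sex`, `age`.
#' @param protocol List of protocol options: `initial_power_w` (default
#'   `NULL`: auto-select the workload that puts the steady-state pulse
#'   mid-nomogram, emulating the tester's initial estimate from age and
#'   apparent fitness; pass a number, e.g. 60-90 W, to fix it), `tau_min`
#'   (HR time constant, minutes), `hr_rest` (pre-test heart rate),
#'   `power_step_w` (granularity of power adjustments), and `hr_drift`
#'   (bpm/min of upward cardiovascular drift; at 5 or more the session
#'   never satisfies the steady-state rule and is capped at 10 minutes).
#' @return List `test` (the `ErgometerTest` actually run) and `result`
#'   (tibble from [estimate_vo2max()]; `vo2max_*` are `NA` with
#'   `out_of_range = TRUE` when the pulse left the tabulated range).
#' @export
simulate_test_session <- function(worker,
                                  protocol = list()) {
  p <- utils::modifyList(list(initial_power_w = NULL, tau_min = 1.2,
                              hr_rest = 70, power_step_w = 15,
                              hr_drift = 0, max_minutes = 10L), protocol,
                         keep.null = TRUE)
  abs_true <- worker$vo2max * worker$body_mass / 1000
  ac <- age_correction_at(worker$age)
  hr_ss_at <- function(power_w) {
    vo2w <- vo2_cost_at(watts_to_kpm(power_w))
    pct <- vo2w * ac / abs_true
    tab <- ar_nomogram()$nomogram
    row <- tab[tab$sex == as.character(worker$sex), ]
    row$hr_at_half_max + (pct - 0.5) * 2 * (row$hr_max_ref - row$hr_at_half_max)
  }
  power_for_target <- function(target_hr) {
    tab <- ar_nomogram()$nomogram
    row <- tab[tab$sex == as.character(worker$sex), ]
    pct <- 0.5 + 0.5 * (target_hr + 3 - row$hr_at_half_max) /
      (row$hr_max_ref - row$hr_at_half_max)
    vo2w <- pct * abs_true / ac
    cost <- ar_nomogram()$vo2_cost
    kpm <- approx(cost$vo2_l_min, cost$workload_kpm, xout = vo2w, rule = 2)$y
    ceiling((kpm / 6.12) / p$power_step_w) * p$power_step_w
  }

  # the tester's initial power estimate "from age and estimated fitness":
  # auto-select a workload putting the steady-state pulse mid-nomogram
  power <- if (is.null(p$initial_power_w)) {
    max(60, power_for_target(137))
  } else {
    p$initial_power_w
  }
  target <- hr_ss_at(power)
  readings <- numeric(0)
  state <- p$hr_rest
  adjusted <- FALSE
  for (m in seq_len(p$max_minutes)) {
    state <- target - (target - state) * exp(-1 / p$tau_min)
    readings[m] <- round(state + p$hr_drift * m)
    if (m == 1) {
      goal <- power_adjustment_needed(readings[1], hr_max_tanaka(worker$age))
      if (!is.null(goal)) {
        power <- max(power_for_target(goal), power + p$power_step_w)
        target <- hr_ss_at(power)
        adjusted <- TRUE
      }
    }
  }
  test <- list(power_w = power, cadence = 60, hr_readings = readings,
               sex = as.character(worker$sex), age = worker$age,
               body_mass = worker$body_mass, power_adjusted = adjusted)
  result <- tryCatch(estimate_vo2max(test),
                     workhrr_range_error = function(e) {
                       tibble(vo2max_abs = NA_real_, vo2max_rel = NA_real_,
                              steady_state = TRUE, power_adjusted = adjusted,
                              termination_minute = NA_integer_)
                     })
  result$out_of_range <- is.na(result$vo2max_abs) & result$steady_state
  list(test = test, result = result)
}

#' Eligibility screen for the fitness test
#'
#' Workers are excluded from the cycle-ergometer test for hypertension
#' (systolic >= 160 or diastolic >= 100 mmHg), self-reported angina, use of
#' heart or lung medicine, a history of disc herniation, fever on the day
#' of testing, or pregnancy; adhesive allergy excludes the heart-rate
#' measurement instead. Clinical fields not carried by the worker table are
#' supplied as arguments.
#'
#' @param worker One-row worker tibble (unused fields ignored).
#' @param systolic,diastolic Blood pressure, mmHg (`NA` = not measured).
#' @param angina,heart_lung_medication,disc_herniation,fever,pregnant
#'   Logical screen items.
#' @return `TRUE` if eligible; otherwise `FALSE` with a `reasons` attribute.
#' @export
fitness_eligible <- function(worker, systolic = NA, diastolic = NA,
                             angina = FALSE, heart_lung_medication = FALSE,
                             disc_herniation = FALSE, fever = FALSE,
                             pregnant = FALSE) {
  reasons <- character(0)
  if (!is.na(systolic) && systolic >= 160) reasons <- c(reasons, "systolic >= 160")
  if (!is.na(diastolic) && diastolic >= 100) reasons <- c(reasons, "diastolic >= 100")
  if (isTRUE(angina)) reasons <- c(reasons, "angina")
  if (isTRUE(heart_lung_medication)) reasons <- c(reasons, "heart/lung medicine")
  if (isTRUE(disc_herniation)) reasons <- c(reasons, "disc herniation")
  if (isTRUE(fever)) reasons <- c(reasons, "fever")
  if (isTRUE(pregnant)) reasons <- c(reasons, "pregnancy")
  ok <- length(reasons) == 0
  if (!ok) attr(ok, "reasons") <- reasons
  ok
}
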