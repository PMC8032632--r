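#' Simulate a worker cohort
#'
#' Draws worker-level attributes from the scenario's demographic model:
#' truncated-normal age and fitness with a configurable negative correlation,
#' categorical sex/occupation/shift/self-rated health, medication use,
#' lognormal steps per hour, body mass, the worker's true minimum (sleeping)
#' heart rate, and the measurement plan (number of measured days and valid
#' work hours per day). Deterministic given the configuration and its seed.
#'
#' @param config An [scenario_config()] object.
#' @return A tibble, one row per worker, with columns `worker_id`, `age`,
#'   `sex`, `occupation`, `shift`, `self_rated_health`, `medication`,
#'   `steps_per_hour`, `vo2max`, `body_mass`, `hr_min_true`, `n_days`,
#'   `work_h_per_day`.
#' @export
simulate_cohort <- function(config) {
  validate_scenario(config)
  n <- config$n_workers
  set.seed(derive_seed(config$seed, 1L))
  av <- draw_age_fitness(n, config)
  sex <- factor(ifelse(runif(n) < config$p_female, "female", "male"),
                levels = c("female", "male"))
  occupation <- factor(sample(names(config$occupation_probs), n, TRUE,
                              prob = config$occupation_probs),
                       levels = names(config$occupation_probs))
  shift <- factor(sample(names(config$shift_probs), n, TRUE,
                         prob = config$shift_probs),
                  levels = names(config$shift_probs))
  srh <- sample(seq_along(config$srh_probs), n, TRUE, prob = config$srh_probs)
  medication <- runif(n) < config$p_medication
  steps <- rlnorm(n, config$steps$meanlog, config$steps$sdlog)
  bm <- config$body_mass
  body_mass <- rnorm_trunc(n, bm$mean, bm$sd, bm$min, bm$max)
  hm <- config$hr_min_true
  hr_min_true <- rnorm_trunc(n, hm$mean, hm$sd, hm$min, hm$max)
  n_days <- as.integer(sample(as.integer(names(config$days_probs)), n, TRUE,
                              prob = config$days_probs))
  wh <- config$work_hours_per_day
  work_h <- rnorm_trunc(n, wh$mean, wh$sd, wh$min, wh$max)

  tibble(worker_id = sprintf("W%04d", seq_len(n)),
         age = round(av$age),
         sex = sex, occupation = occupation, shift = shift,
         self_rated_health = as.integer(srh), medication = medication,
         steps_per_hour = steps, vo2max = av$vo2max, body_mass = body_mass,
         hr_min_true = hr_min_true, n_days = n_days, work_h_per_day = work_h)
}

# Per-worker centred covariate offsets on the %HRR scale.
worker_offsets <- function(cohort, config) {
  off <- config$covariate_offsets
  raw <- ifelse(cohort$sex == "female", off$sex_female, 0) +
    off$occupation[as.character(cohort$occupation)] +
    ifelse(cohort$shift != "fixed_day", off$shift_nonday, 0) +
    ifelse(cohort$medication, off$medication, 0)
  unname(raw)
}

# Injected slope per worker for one outcome (scalar, or per age band under
# an interaction scenario).
worker_slopes <- function(cohort, config, scalar, bands) {
  ai <- config$age_interaction
  if (is.null(ai)) return(rep(scalar, nrow(cohort)))
  band <- cut(cohort$age, breaks = ai$breaks, labels = ai$labels, right = TRUE)
  bands[as.integer(band)]
}

#' Simulate per-worker workload outcomes (metric level)
#'
#' Draws the three per-worker workload outcomes directly on the outcome
#' scale: mean %HRR and maximum %HRR as linear functions of fitness plus
#' centred covariate offsets and correlated Gaussian residuals, and the
#' work-time composition on the ilr scale (then inverse-transformed to a
#' proportion). Intercepts and residual SDs come from
#' [calibrate_scenario()], so cohort summaries match the configured targets
#' in expectation, and the injected fitness slopes are recovered by the
#' unadjusted regression because all covariate offsets are generated
#' independently of fitness.
#'
#' @param cohort Output of [simulate_cohort()].
#' @param config The same scenario used to generate `cohort`.
#' @return A tibble (one row per worker) with `worker_id`, `hrr_mean`,
#'   `hrr_max_1min`, `prop_above_30`, `work_time_valid_h`, `n_valid_days`
#'   and `valid`. The noise-free per-worker values and the injected slopes
#'   are attached as attribute `"ground_truth"` (a list with a `workers`
#'   tibble, the slope vectors and the seed).
#' @export
simulate_outcomes <- function(cohort, config) {
  validate_scenario(config)
  cal <- calibrate_scenario(config)
  n <- nrow(cohort)
  set.seed(derive_seed(config$seed, 2L))

  off <- worker_offsets(cohort, config)
  off_c <- off - cal$offset_mean                       # centred, %HRR scale
  off_z <- off * cal$z_per_pct - cal$offset_mean_z     # centred, ilr scale
  v_c <- cohort$vo2max - cal$e_vo2

  b_mean <- worker_slopes(cohort, config, config$hrr_mean$slope,
                          config$age_interaction$slopes_mean)
  b_max <- worker_slopes(cohort, config, config$hrr_max$slope,
                         config$age_interaction$slopes_max)
  b_z <- if (is.null(config$age_interaction)) {
    rep(cal$beta_z, n)
  } else {
    cal$beta_z_bands[as.integer(cut(cohort$age,
                                    breaks = config$age_interaction$breaks,
                                    labels = FALSE, right = TRUE))]
  }

  mu_mean <- config$hrr_mean$mean + b_mean * v_c + off_c
  mu_max <- config$hrr_max$mean + b_max * v_c + off_c
  mu_z <- cal$z_median + b_z * v_c + off_z

  # correlated residuals: max and composition share a component with mean
  r12 <- unname(config$residual_cor["mean_max"])
  r13 <- unname(config$residual_cor["mean_comp"])
  e1 <- rnorm(n)
  e2 <- r12 * e1 + sqrt(1 - r12^2) * rnorm(n)
  e3 <- r13 * e1 + sqrt(1 - r13^2) * rnorm(n)

  hrr_mean <- pmin(pmax(mu_mean + cal$sd_eps_mean * e1, 0), 100)
  hrr_max <- pmin(pmax(mu_max + cal$sd_eps_max * e2, 0), 100)
  hrr_max <- pmax(hrr_max, hrr_mean)      # exceedance level >= mean workload
  z_obs <- mu_z + cal$sd_eps_z * e3
  p_above <- ilr_inverse(z_obs)

  work_h <- cohort$n_days * cohort$work_h_per_day

  out <- tibble(worker_id = cohort$worker_id,
                hrr_mean = hrr_mean,
                hrr_max_1min = hrr_max,
                prop_above_30 = p_above,
                work_time_valid_h = work_h,
                n_valid_days = cohort$n_days,
                valid = TRUE)
  gt <- tibble(worker_id = cohort$worker_id,
               true_hrr_mean = mu_mean, true_hrr_max = mu_max,
               true_z = mu_z, true_prop = ilr_inverse(mu_z),
               slope_mean = b_mean, slope_max = b_max, slope_z = b_z)
  attr(out, "ground_truth") <- list(workers = gt, seed = config$seed,
                                    calibration = cal)
  out
}

#' Simulate a full analysis-ready cohort
#'
#' Convenience wrapper: [simulate_cohort()] + [simulate_outcomes()] +
#' [build_analysis_rows()].
#'
#' @param config An [scenario_config()] object.
#' @return List with `workers`, `summaries`, `rows` (analysis rows ready for
#'   [fit_model()]) and `ground_truth`.
#' @export
simulate_analysis_cohort <- function(config) {
  workers <- simulate_cohort(config)
  summaries <- simulate_outcomes(workers, config)
  rows <- build_analysis_rows(workers, summaries)
  list(workers = workers, summaries = summaries, rows = rows,
       ground_truth = attr(summaries, "ground_truth"))
}
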