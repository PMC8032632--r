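# covariates of the adjusted model (the stratifying one is removed when
# stratifying); self-rated health enters as its 1-5 ordinal code
adjusted_covariates <- c("age", "sex", "self_rated_health", "shift_nonday",
                         "medication", "occupation")

#' Assemble analysis rows from worker and workload tables
#'
#' Joins the worker covariates to the per-worker workload summaries,
#' derives the binary shift indicator (non-fixed-day work), and converts
#' the work-time composition to its ilr coordinate after zero replacement.
#'
#' @param workers Tibble from [simulate_cohort()] (or equivalent real
#'   covariate table with the same columns).
#' @param summaries Tibble of workload summaries (`worker_id`, `hrr_mean`,
#'   `hrr_max_1min`, `prop_above_30`, `work_time_valid_h`, `valid`).
#' @return Tibble of analysis rows (invalid workers dropped) with outcome
#'   columns `hrr_mean`, `hrr_max_1min`, `ilr_z` and covariates
#'   `vo2max_rel`, `age`, `sex`, `self_rated_health`, `shift_nonday`,
#'   `medication`, `occupation`, `steps_per_hour`.
#' @export
build_analysis_rows <- function(workers, summaries) {
  rows <- dplyr::inner_join(workers, summaries, by = "worker_id")
  rows <- rows[rows$valid & !is.na(rows$hrr_mean), ]
  total_s <- rows$work_time_valid_h * 3600
  comp <- zero_replace(rows$prop_above_30 * total_s,
                       (1 - rows$prop_above_30) * total_s, total_s)
  tibble(worker_id = rows$worker_id,
         vo2max_rel = rows$vo2max,
         hrr_mean = rows$hrr_mean,
         hrr_max_1min = rows$hrr_max_1min,
         prop_above_30 = rows$prop_above_30,
         ilr_z = ilr_two_part(comp$p_above),
         age = rows$age,
         sex = rows$sex,
         self_rated_health = rows$self_rated_health,
         shift_nonday = factor(ifelse(rows$shift == "fixed_day",
                                      "fixed_day", "nonday"),
                               levels = c("fixed_day", "nonday")),
         medication = rows$medication,
         occupation = rows$occupation,
         steps_per_hour = rows$steps_per_hour)
}

# drop factor covariates with fewer than two observed levels (degenerate in
# a stratum); warn so the omission is visible
drop_degenerate <- function(rows, covs) {
  keep <- vapply(covs, function(cv) {
    x <- rows[[cv]]
    if (is.factor(x) || is.character(x) || is.logical(x)) {
      length(unique(x[!is.na(x)])) >= 2
    } else {
      TRUE
    }
  }, logical(1))
  if (any(!keep)) {
    warning("dropping degenerate covariate(s): ",
            paste(covs[!keep], collapse = ", "), call. = FALSE)
  }
  covs[keep]
}

#' Fit the fitness-workload regression for one outcome
#'
#' Ordinary least-squares regression of an outcome on cardiorespiratory
#' fitness, unadjusted or adjusted for the confounder set (age, sex,
#' self-rated health, shift work, prescription medication, occupation;
#' retained regardless of significance). Complete-case analysis. Reports
#' the fitness slope with its Wald-type 95% confidence interval.
#'
#' @param rows Analysis rows from [build_analysis_rows()].
#' @param outcome One of `"hrr_mean"`, `"hrr_max_1min"`, `"ilr_z"`.
#' @param adjusted Include the confounder set?
#' @param exclude_covariate Covariate(s) to omit from the adjusted set
#'   (used when stratifying by a model covariate).
#' @param min_rows Minimum complete rows required (default 30).
#' @param label Optional model label for the output.
#' @return One-row tibble of class `EffectEstimate`-like: `model`,
#'   `outcome`, `estimate` (slope per 1 mlO2/min/kg), `ci_lo`, `ci_hi`,
#'   `p`, `n`, `stratum`. The fitted `lm` object is attached as attribute
#'   `"fit"` for downstream back-transformation.
#' @export
fit_model <- function(rows, outcome = c("hrr_mean", "hrr_max_1min", "ilr_z"),
                      adjusted = FALSE, exclude_covariate = NULL,
                      min_rows = 30, label = NULL) {
  outcome <- match.arg(outcome)
  covs <- if (adjusted) {
    setdiff(adjusted_covariates, exclude_covariate)
  } else {
    character(0)
  }
  vars <- c(outcome, "vo2max_rel", covs)
  cc <- rows[complete.cases(rows[, vars]), , drop = FALSE]
  if (nrow(cc) < min_rows) {
    stop(sprintf("only %d complete rows (need >= %d).", nrow(cc), min_rows),
         call. = FALSE)
  }
  covs <- drop_degenerate(cc, covs)
  fml <- stats::reformulate(c("vo2max_rel", covs), response = outcome)
  fit <- lm(fml, data = cc)
  ci <- confint(fit, "vo2max_rel", level = 0.95)
  out <- tibble(
    model = label %||% if (adjusted) "adjusted" else "unadjusted",
    outcome = outcome,
    estimate = unname(coef(fit)["vo2max_rel"]),
    ci_lo = ci[1], ci_hi = ci[2],
    p = summary(fit)$coefficients["vo2max_rel", "Pr(>|t|)"],
    n = nrow(cc),
    stratum = NA_character_)
  attr(out, "fit") <- fit
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Test the fitness-by-moderator interaction
#'
#' Adds a product term between fitness and a continuous moderator (default
#' age) to the adjusted model. Both variables are mean-centred before
#' multiplication so the main effects keep their interpretation at the
#' sample means; the product-term coefficient itself is invariant to
#' centring.
#'
#' @inheritParams fit_model
#' @param moderator Continuous moderator column name (default `"age"`).
#' @return One-row tibble for the product term (`estimate` is the change in
#'   the fitness slope per unit of the moderator), with the fitted model as
#'   attribute `"fit"`.
#' @export
interaction_test <- function(rows, outcome = c("hrr_mean", "hrr_max_1min",
                                               "ilr_z"),
                             moderator = "age") {
  outcome <- match.arg(outcome)
  covs <- setdiff(adjusted_covariates, moderator)
  vars <- c(outcome, "vo2max_rel", moderator, covs)
  cc <- rows[complete.cases(rows[, vars]), , drop = FALSE]
  covs <- drop_degenerate(cc, covs)
  cc$.v_c <- cc$vo2max_rel - mean(cc$vo2max_rel)
  cc$.m_c <- cc[[moderator]] - mean(cc[[moderator]])
  fml <- stats::reformulate(c(".v_c", ".m_c", ".v_c:.m_c", covs),
                            response = outcome)
  fit <- lm(fml, data = cc)
  sm <- summary(fit)$coefficients
  term <- ".v_c:.m_c"
  ci <- confint(fit, term, level = 0.95)
  out <- tibble(model = "interaction",
                outcome = outcome,
                estimate = unname(coef(fit)[term]),
                ci_lo = ci[1], ci_hi = ci[2],
                p = sm[term, "Pr(>|t|)"],
                n = nrow(cc),
                stratum = paste0("vo2max x ", moderator))
  attr(out, "fit") <- fit
  out
}

#' Stratified fitness-workload estimates
#'
#' Fits the adjusted model within strata of age (quartiles or pinned
#' bands), occupation, or steps-per-hour quartiles, excluding the
#' stratifying variable from the covariate set. Quartile boundaries are
#' sample quantiles (type 7) of the analysed rows unless pinned `breaks`
#' are supplied.
#'
#' @inheritParams fit_model
#' @param by `"age_quartiles"`, `"occupation"` or `"steps_quartiles"`.
#' @param breaks Optional pinned numeric breaks for the quartile-based
#'   stratifiers (e.g. `c(-Inf, 37, 45, 51, Inf)` for the published age
#'   bands), with optional `labels`.
#' @param labels Optional stratum labels matching `breaks`.
#' @param min_n Strata smaller than this are flagged `unstable` (default
#'   20) and skipped if smaller than the model needs.
#' @return Tibble of per-stratum estimates with `stratum`, `n` and
#'   `unstable` columns; stratum sizes partition the analysed rows.
#' @export
stratify <- function(rows, by = c("age_quartiles", "occupation",
                                  "steps_quartiles"),
                     outcome = c("hrr_mean", "hrr_max_1min", "ilr_z"),
                     breaks = NULL, labels = NULL, min_n = 20) {
  by <- match.arg(by)
  outcome <- match.arg(outcome)
  if (by == "occupation") {
    strata <- rows$occupation
    exclude <- "occupation"
  } else {
    var <- if (by == "age_quartiles") rows$age else rows$steps_per_hour
    if (is.null(breaks)) {
      qs <- quantile(var, c(0.25, 0.5, 0.75), type = 7, na.rm = TRUE)
      breaks <- c(-Inf, qs, Inf)
      labels <- labels %||% c(sprintf("<=%.1f", qs[1]),
                              sprintf("%.1f-%.1f", qs[1], qs[2]),
                              sprintf("%.1f-%.1f", qs[2], qs[3]),
                              sprintf(">%.1f", qs[3]))
    }
    strata <- cut(var, breaks = breaks, labels = labels, right = TRUE)
    exclude <- if (by == "age_quartiles") "age" else NULL
  }
  res <- list()
  for (lv in levels(factor(strata))) {
    sub <- rows[!is.na(strata) & strata == lv, , drop = FALSE]
    n_s <- nrow(sub)
    est <- tryCatch(
      suppressWarnings(
        fit_model(sub, outcome = outcome, adjusted = TRUE,
                  exclude_covariate = exclude, min_rows = max(10, min_n / 2),
                  label = paste0("stratified:", by))),
      error = function(e) {
        tibble(model = paste0("stratified:", by), outcome = outcome,
               estimate = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
               p = NA_real_, n = n_s, stratum = NA_character_)
      })
    est$stratum <- lv
    est$n <- n_s
    est$unstable <- n_s < min_n
    res[[lv]] <- est
  }
  dplyr::bind_rows(res)
}

#' Back-transform the ilr-scale composition effect to percentage points
#'
#' Expresses the fitted ilr-scale fitness slope as the absolute change in
#' the percentage of work time spent at or above the cut-off: the fitted
#' ilr prediction at the covariate means (the mean of the fitted values, in
#' a linear model) is inverse-transformed at mean fitness and at mean
#' fitness + 1, and the difference of the two proportions is reported in
#' percentage points. The confidence limits are carried through the same
#' monotone map.
#'
#' @param est One-row estimate from [fit_model()] (outcome `"ilr_z"`),
#'   carrying its fitted model as attribute `"fit"`.
#' @return One-row tibble: `delta_pct`, `ci_lo`, `ci_hi` (percentage points
#'   of work time per unit fitness), `z_ref` (evaluation point).
#' @export
backtransform_delta_pct <- function(est) {
  fit <- attr(est, "fit")
  if (is.null(fit)) stop("`est` must carry its fitted model.", call. = FALSE)
  z0 <- mean(fitted(fit))
  map <- function(b) 100 * (ilr_inverse(z0 + b) - ilr_inverse(z0))
  tibble(delta_pct = map(est$estimate),
         ci_lo = map(est$ci_lo),
         ci_hi = map(est$ci_hi),
         z_ref = z0)
}
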