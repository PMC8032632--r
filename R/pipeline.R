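#' Run the full simulate-to-estimates pipeline
#'
#' Orchestrates the stages end to end into an output directory: cohort
#' simulation, workload outcomes (metric-level draws, or beat-level streams
#' pushed through quality control and the %HRR pipeline), simulated fitness
#' test sessions, analysis-row assembly, and the regression surface
#' (unadjusted and adjusted models for the three outcomes, the
#' back-transformed composition effect, the fitness-by-age interaction and
#' the stratified analyses). Writes CSV outputs plus a JSON manifest with
#' seeds, file inventory and checksums; re-running with the same
#' configuration and seed reproduces identical outputs.
#'
#' @param config An [scenario_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Optional seed overriding `config$seed`.
#' @param strata Character vector of stratified analyses to run (subset of
#'   `"age_quartiles"`, `"occupation"`, `"steps_quartiles"`).
#' @param fitness_sessions Simulate ergometer test sessions and write
#'   `fitness.csv` (default `TRUE`).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL,
                         strata = c("age_quartiles", "occupation",
                                    "steps_quartiles"),
                         fitness_sessions = TRUE) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  validate_scenario(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  put <- function(df, name) {
    f <- file.path(out_dir, name)
    write.csv(df, f, row.names = FALSE)
    paths <<- c(paths, f)
    f
  }

  workers <- simulate_cohort(config)
  put(workers, "workers.csv")

  if (config$fidelity == "metric_level") {
    summaries <- simulate_outcomes(workers, config)
    gt <- attr(summaries, "ground_truth")$workers
  } else {
    sim <- simulate_beat_cohort(config)
    res <- workload_from_streams(sim$streams, sim$diary, sim$workers)
    summaries <- res$summaries
    gt <- sim$ground_truth
    jsonlite::write_json(res$qc, file.path(out_dir, "qc_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths <- c(paths, file.path(out_dir, "qc_report.json"))
  }
  put(summaries, "workload_summary.csv")
  put(gt, "ground_truth.csv")

  if (fitness_sessions) {
    fits <- dplyr::bind_rows(lapply(seq_len(nrow(workers)), function(i) {
      r <- simulate_test_session(workers[i, ])$result
      dplyr::bind_cols(tibble(worker_id = workers$worker_id[i],
                              vo2max_true = workers$vo2max[i]), r)
    }))
    put(fits, "fitness.csv")
  }

  rows <- build_analysis_rows(workers, summaries)
  ests <- list()
  for (oc in c("hrr_mean", "hrr_max_1min", "ilr_z")) {
    for (adj in c(FALSE, TRUE)) {
      e <- fit_model(rows, outcome = oc, adjusted = adj)
      if (oc == "ilr_z") {
        bt <- backtransform_delta_pct(e)
        e$delta_pct <- bt$delta_pct
        e$delta_ci_lo <- bt$ci_lo
        e$delta_ci_hi <- bt$ci_hi
      }
      ests[[length(ests) + 1]] <- e
    }
    ests[[length(ests) + 1]] <- interaction_test(rows, outcome = oc)
    for (st in strata) {
      ests[[length(ests) + 1]] <- stratify(rows, by = st, outcome = oc)
    }
  }
  estimates <- dplyr::bind_rows(ests)
  put(estimates, "estimates.csv")

  cfg_file <- file.path(out_dir, "config.json")
  jsonlite::write_json(config[setdiff(names(config), "")], cfg_file,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  paths <- c(paths, cfg_file)
  manifest <- list(
    package_version = as.character(utils::packageVersion("workhrr")),
    seed = config$seed,
    fidelity = config$fidelity,
    n_workers = config$n_workers,
    config_md5 = unname(tools::md5sum(cfg_file)),
    files = lapply(stats::setNames(paths, basename(paths)),
                   function(f) unname(tools::md5sum(f))),
    n_analysis_rows = nrow(rows))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Human-readable summary of a pipeline run
#'
#' Renders the estimates table of a finished run as a compact text report:
#' unadjusted and adjusted slopes with confidence intervals for the three
#' outcomes (the composition effect both on the ilr scale and back-
#' transformed to percentage points of work time), the interaction terms,
#' and the stratified estimates with unstable strata marked.
#'
#' @param out_dir Directory written by [run_pipeline()].
#' @return The estimates tibble, invisibly.
#' @export
report_run <- function(out_dir) {
  f <- file.path(out_dir, "estimates.csv")
  if (!file.exists(f)) {
    stop("no estimates.csv in `out_dir`; run run_pipeline() first.",
         call. = FALSE)
  }
  est <- as_tibble(read.csv(f, stringsAsFactors = FALSE))
  fmt <- function(e, lo, hi) sprintf("%6.2f [%6.2f, %6.2f]", e, lo, hi)
  cat("Fitness-workload estimates (slope per 1 mlO2/min/kg)\n")
  cat(strrep("-", 60), "\n")
  for (oc in unique(est$outcome)) {
    cat(oc, "\n")
    sub <- est[est$outcome == oc, ]
    for (i in seq_len(nrow(sub))) {
      r <- sub[i, ]
      lab <- r$model
      if (!is.na(r$stratum) && r$stratum != "") {
        lab <- paste0(lab, " [", r$stratum, "]")
      }
      if (is.na(r$estimate)) {
        cat(sprintf("  %-38s %s (n=%d)\n", lab, "unstable/suppressed", r$n))
        next
      }
      line <- sprintf("  %-38s %s  p=%.3g n=%d", lab,
                      fmt(r$estimate, r$ci_lo, r$ci_hi), r$p, r$n)
      if (isTRUE(!is.na(r$unstable) & r$unstable)) {
        line <- paste(line, "(unstable)")
      }
      cat(line, "\n")
      if (!is.null(r$delta_pct) && !is.na(r$delta_pct)) {
        cat(sprintf("  %-38s %s percentage points of work time\n", "  as delta%",
                    fmt(r$delta_pct, r$delta_ci_lo, r$delta_ci_hi)))
      }
    }
  }
  invisible(est)
}
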