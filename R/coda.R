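#' Isometric log-ratio coordinate of a two-part time-use composition
#'
#' Maps the proportion of work time spent at or above the workload cut-off
#' onto the real line. For a two-part composition (above, below) the single
#' ilr balance is `z = log(p / (1 - p)) / sqrt(2)`; the sign convention is
#' that positive values mean more work time above the cut-off than below it.
#'
#' @param p Proportion of time in the "above" part, strictly inside (0, 1).
#'   Apply [zero_replace()] first if a part may be empty.
#' @return Numeric vector of ilr coordinates.
#' @seealso [ilr_inverse()], [zero_replace()], [backtransform_delta_pct()]
#' @export
#' @examples
#' ilr_two_part(0.5)                      # 0: equal time above and below
#' ilr_inverse(ilr_two_part(0.47))        # round trip
ilr_two_part <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    stop("`p` must lie strictly inside (0, 1); run zero_replace() first.",
         call. = FALSE)
  }
  log(p / (1 - p)) / sqrt(2)
}

#' @rdname ilr_two_part
#' @param z ilr coordinate(s).
#' @export
ilr_inverse <- function(z) {
  plogis(sqrt(2) * z)
}

#' Replace an empty part of the work-time composition
#'
#' A worker who never (or always) exceeds the workload cut-off has a zero
#' part, which the log-ratio cannot handle. The zero part is replaced by the
#' duration of a single 4 Hz sample (0.25 s) relative to the total, and the
#' other part is shrunk so the two proportions still sum to one. Workers with
#' both parts positive are returned unchanged.
#'
#' @param t_above,t_below Seconds of valid work time at/above and below the
#'   cut-off. Must satisfy `t_above + t_below == total`.
#' @param total Total seconds of valid work time (> 0).
#' @param sample_s Duration of one sample, seconds (default 0.25, i.e. 4 Hz).
#' @return A tibble with columns `p_above` and `p_below`, each row summing
#'   to exactly one.
#' @export
zero_replace <- function(t_above, t_below, total, sample_s = 0.25) {
  if (any(total <= 0)) {
    stop("`total` must be positive; exclude zero-time workers upstream.",
         call. = FALSE)
  }
  if (any(abs(t_above + t_below - total) > 1e-6 * pmax(total, 1))) {
    stop("`t_above + t_below` must equal `total`.", call. = FALSE)
  }
  p_above <- t_above / total
  delta <- sample_s / total
  p_above <- ifelse(t_above <= 0, delta, p_above)
  p_above <- ifelse(t_below <= 0, 1 - delta, p_above)
  tibble(p_above = p_above, p_below = 1 - p_above)
}

#' ilr-scale slope that back-transforms to a target absolute change
#'
#' Inverts the back-transform contrast used by [backtransform_delta_pct()]:
#' given a reference proportion and a target change in percentage points of
#' work time per one-unit increase in fitness, returns the ilr-scale slope
#' whose +1-unit contrast at the reference composition reproduces exactly
#' that change. Used by the synthetic generator to inject composition
#' effects on the scale the models are fitted on.
#'
#' @param delta_pct Target change, percentage points of work time per unit
#'   of fitness (e.g. -1.8).
#' @param p_ref Reference proportion of time above the cut-off at which the
#'   contrast is evaluated.
#' @return ilr-scale slope (per unit fitness).
#' @export
ilr_slope_for_delta_pct <- function(delta_pct, p_ref) {
  p_target <- p_ref + delta_pct / 100
  if (p_target <= 0 || p_target >= 1) {
    stop("target proportion outside (0, 1); reduce `delta_pct`.", call. = FALSE)
  }
  ilr_two_part(p_target) - ilr_two_part(p_ref)
}
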