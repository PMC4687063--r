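#' Saccadic gain
#'
#' Gain is saccade amplitude divided by the target displacement that evoked
#' it; the signed ratio, so a correct-direction response gives a positive
#' gain and 1.0 is perfectly accurate.
#'
#' @param saccade_amplitude_deg Signed saccade amplitude(s), deg.
#' @param step_amplitude_deg Signed target step(s), deg; must be non-zero.
#' @return Numeric gain(s).
#' @export
#' @examples
#' compute_gain(8, 10)    # 0.8
#' compute_gain(-9, -10)  # 0.9
compute_gain <- function(saccade_amplitude_deg, step_amplitude_deg) {
  if (any(step_amplitude_deg == 0, na.rm = TRUE)) {
    abort("`step_amplitude_deg` must be non-zero",
          class = "sacclong_invalid_argument")
  }
  saccade_amplitude_deg / step_amplitude_deg
}

#' Segment a trace into stimulus-response trials
#'
#' Pairs every target step with the primary saccadic response: the first
#' detected saccade whose onset falls inside the response window after the
#' step and whose amplitude reaches the minimum response amplitude. Latency
#' is onset minus step time. Responses faster than the anticipation bound
#' (the lower edge of the window) are marked `anticipatory` and excluded
#' from latency/gain summaries; steps with no qualifying saccade are marked
#' `no_response`.
#'
#' For antisaccade recordings, where the target returns to fixation between
#' presentations, only steps away from fixation constitute trials
#' (`steps = "eccentric"`); the return steps are bookkeeping. A response is
#' scored as a direction error when its primary saccade goes toward the
#' target rather than away from it.
#'
#' @param trace A `gaze_trace` for a prosaccade or antisaccade session.
#' @param events Detected saccades from [detect_saccades()].
#' @param task Task label; defaults to the trace's task attribute.
#' @param window_ms Response window after each step, `c(lower, upper)` ms;
#'   onsets before the lower bound are anticipatory.
#' @param min_response_amplitude_deg Minimum amplitude for a saccade to count
#'   as the primary response. Default: half the smallest step magnitude for
#'   prosaccades, 2 deg for antisaccades (smaller movements are not scored).
#' @param steps `"all"` (every target step is a trial) or `"eccentric"`
#'   (only steps landing away from fixation).
#'
#' @return A tibble with one row per trial: `trial`, `step_time_ms`,
#'   `step_amplitude_deg`, `latency_ms`, `response_amplitude_deg`, `gain`
#'   (prosaccade only), `response_direction_correct` (antisaccade only) and
#'   `exclusion_reason` (`"none"`, `"anticipatory"` or `"no_response"`).
#' @export
segment_trials <- function(trace, events,
                           task = NULL,
                           window_ms = c(80, 700),
                           min_response_amplitude_deg = NULL,
                           steps = NULL) {
  check_trace_frame(trace)
  task <- task %||% attr(trace, "task") %||% "prosaccade"
  if (!task %in% c("prosaccade", "antisaccade")) {
    abort("`segment_trials()` applies to prosaccade or antisaccade traces",
          class = "sacclong_invalid_argument")
  }
  steps <- steps %||% if (task == "antisaccade") "eccentric" else "all"
  steps <- match.arg(steps, c("all", "eccentric"))

  d <- diff(trace$target_deg)
  idx <- which(abs(d) > 0.5)
  if (length(idx) == 0) {
    abort("no target steps found in the trace",
          class = "sacclong_invalid_input")
  }
  step_time <- trace$time_ms[idx + 1L]
  step_amp <- d[idx]
  landing <- trace$target_deg[idx + 1L]
  if (steps == "eccentric") {
    keep <- abs(landing) > 0.5
    step_time <- step_time[keep]; step_amp <- step_amp[keep]
  }
  n <- length(step_time)
  if (n == 0) {
    abort("no eccentric target steps found in the trace",
          class = "sacclong_invalid_input")
  }

  min_amp <- min_response_amplitude_deg %||%
    if (task == "antisaccade") 2 else min(abs(step_amp)) / 2

  lat <- resp_amp <- rep(NA_real_, n)
  reason <- rep("no_response", n)
  for (i in seq_len(n)) {
    cand <- which(events$onset_ms > step_time[i] &
                  events$onset_ms <= step_time[i] + window_ms[2] &
                  abs(events$amplitude_deg) >= min_amp)
    if (length(cand) == 0) next
    j <- cand[1]
    lat[i] <- events$onset_ms[j] - step_time[i]
    resp_amp[i] <- events$amplitude_deg[j]
    reason[i] <- if (lat[i] < window_ms[1]) "anticipatory" else "none"
  }
  scored <- reason == "none"

  out <- tibble(
    trial = seq_len(n),
    step_time_ms = step_time,
    step_amplitude_deg = step_amp,
    latency_ms = lat,
    response_amplitude_deg = resp_amp,
    exclusion_reason = reason
  )
  if (task == "prosaccade") {
    out$gain <- ifelse(scored, compute_gain(resp_amp, step_amp), NA_real_)
  } else {
    out$response_direction_correct <-
      ifelse(scored, sign(resp_amp) == -sign(step_amp), NA)
  }
  out
}
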