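#' HSEM-alpha: slope of the peak-duration-amplitude regression
#'
#' Peak duration is a saccade's amplitude divided by its peak velocity.
#' HSEM-alpha (horizontal saccadic eye movement alpha) is the
#' ordinary-least-squares slope of peak duration (s) regressed on absolute
#' amplitude (deg). For saccades whose peak velocity has saturated at the
#' main-sequence asymptote the relation is exactly linear with slope
#' `1 / vmax`, which is why HSEM-alpha tracks the inverse of the asymptotic
#' peak velocity.
#'
#' @param events Saccades with `amplitude_deg` and either `peak_duration_s`
#'   or `peak_velocity_dps` columns.
#' @param min_n Minimum number of saccades for the fit.
#'
#' @return A one-row tibble: `hsem_alpha` (s/deg), `intercept_s`,
#'   `r_squared`, `n_saccades`, `defined`. When the design is degenerate
#'   (too few saccades or a single amplitude) `defined` is `FALSE` and the
#'   estimates are `NA`.
#' @export
#' @examples
#' ev <- tibble::tibble(amplitude_deg = c(10, 20),
#'                      peak_duration_s = c(0.025, 0.045))
#' compute_hsem_alpha(ev, min_n = 2)$hsem_alpha # 0.002 s/deg
compute_hsem_alpha <- function(events, min_n = 10) {
  a <- abs(events$amplitude_deg)
  pd <- if ("peak_duration_s" %in% names(events)) {
    events$peak_duration_s
  } else {
    a / events$peak_velocity_dps
  }
  ok <- is.finite(a) & is.finite(pd)
  a <- a[ok]; pd <- pd[ok]
  if (length(a) < min_n || length(unique(round(a, 6))) < 2) {
    return(tibble(hsem_alpha = NA_real_, intercept_s = NA_real_,
                  r_squared = NA_real_, n_saccades = length(a),
                  defined = FALSE))
  }
  fit <- lm(pd ~ a)
  tibble(
    hsem_alpha = unname(coef(fit)[2]),
    intercept_s = unname(coef(fit)[1]),
    r_squared = summary(fit)$r.squared,
    n_saccades = length(a),
    defined = TRUE
  )
}

#' Antisaccade direction-error rate
#'
#' Percentage of scoreable antisaccade trials on which the primary saccade
#' went toward the target instead of away from it. Trials with no response
#' (and anticipatory responses) are excluded from the denominator.
#'
#' @param trials Trial table from [segment_trials()] for an antisaccade
#'   session (must carry `response_direction_correct` and
#'   `exclusion_reason`).
#'
#' @return A one-row tibble: `error_pct` (in \[0, 100\]), `n_errors`,
#'   `n_scoreable`. With zero scoreable trials `error_pct` is `NA` and a
#'   warning is raised.
#' @export
antisaccade_error_rate <- function(trials) {
  stopifnot_msg("response_direction_correct" %in% names(trials),
                msg = "`trials` must come from an antisaccade session")
  scored <- trials[trials$exclusion_reason == "none" &
                     !is.na(trials$response_direction_correct), ]
  n <- nrow(scored)
  if (n == 0) {
    warn("no scoreable antisaccade trials; error rate undefined")
    return(tibble(error_pct = NA_real_, n_errors = 0L, n_scoreable = 0L))
  }
  errs <- sum(!scored$response_direction_correct)
  tibble(error_pct = 100 * errs / n, n_errors = errs, n_scoreable = n)
}

#' Self-paced saccade count and inter-saccadic intervals
#'
#' Counts the refixation saccades (amplitude at least half the separation of
#' the two targets) whose onset falls inside the scoring window, and returns
#' the successive onset-to-onset intervals in seconds.
#'
#' @param events Detected saccades from a self-paced session.
#' @param window_s Scoring window length, seconds (from the start of the
#'   recording).
#' @param min_amplitude_deg Minimum amplitude of a refixation saccade, deg;
#'   half the target separation (10 deg for targets at +/-10) by default.
#'
#' @return A list with `count` (saccades inside the window) and `isi_s`
#'   (numeric vector of inter-saccadic intervals between the counted
#'   refixations). Empty events give `count = 0` and an empty `isi_s`.
#' @export
selfpaced_summary <- function(events, window_s = 30, min_amplitude_deg = 10) {
  refix <- events[abs(events$amplitude_deg) >= min_amplitude_deg, ]
  onsets <- sort(refix$onset_ms[refix$onset_ms <= window_s * 1000])
  list(count = length(onsets), isi_s = diff(onsets) / 1000)
}

#' Summarise one patient visit into scalar session metrics
#'
#' Runs the per-session analyses on the detected events and segmented trials
#' of the (up to) three tasks recorded at one visit, and assembles the
#' scalar summaries used for longitudinal modelling: main-sequence `vmax`
#' and `k`, HSEM-alpha, mean gain, median latency, antisaccade error
#' percentage, self-paced count and mean ISI.
#'
#' Gain is summarised by its mean and latency by its median (the latency
#' distribution has a long right tail); all detected prosaccade-session
#' saccades of at least 1 deg enter the main-sequence and HSEM-alpha fits.
#'
#' @param prosaccade,antisaccade,selfpaced Per-task lists with elements
#'   `events` (and `trials` where applicable), e.g. as returned by
#'   [analyse_trace()]. Any of them may be `NULL` if the task was not
#'   recorded.
#' @param min_fit_n Minimum saccade count for the main-sequence and
#'   HSEM-alpha fits.
#' @param selfpaced_window_s Scoring window of the self-paced task, seconds.
#'
#' @return A one-row tibble of session metrics (`NA` where a task is
#'   missing or a fit is undefined) plus the ISI list as a list-column
#'   `isi_s`.
#' @export
session_metrics <- function(prosaccade = NULL, antisaccade = NULL,
                            selfpaced = NULL, min_fit_n = 10,
                            selfpaced_window_s = 30) {
  out <- tibble(
    vmax_dps = NA_real_, k_deg = NA_real_, hsem_alpha = NA_real_,
    gain = NA_real_, latency_ms = NA_real_,
    antisaccade_error_pct = NA_real_,
    selfpaced_count = NA_integer_, isi_s = list(numeric(0))
  )
  if (!is.null(prosaccade)) {
    ms <- fit_main_sequence(prosaccade$events, min_n = min_fit_n)
    if (ms$converged) { out$vmax_dps <- ms$vmax; out$k_deg <- ms$k }
    hs <- compute_hsem_alpha(prosaccade$events, min_n = min_fit_n)
    if (hs$defined) out$hsem_alpha <- hs$hsem_alpha
    tr <- prosaccade$trials
    if (!is.null(tr)) {
      scored <- tr[tr$exclusion_reason == "none", ]
      if (nrow(scored) > 0) {
        out$gain <- mean(scored$gain, na.rm = TRUE)
        out$latency_ms <- median(scored$latency_ms, na.rm = TRUE)
      }
    }
  }
  if (!is.null(antisaccade) && !is.null(antisaccade$trials)) {
    out$antisaccade_error_pct <-
      antisaccade_error_rate(antisaccade$trials)$error_pct
  }
  if (!is.null(selfpaced)) {
    sp <- selfpaced_summary(selfpaced$events, window_s = selfpaced_window_s)
    out$selfpaced_count <- sp$count
    out$isi_s <- list(sp$isi_s)
  }
  out
}

#' Detect events and segment trials in one call
#'
#' Convenience wrapper running [compute_velocity()], [detect_saccades()] and
#' (for stimulus-driven tasks) [segment_trials()] on a trace.
#'
#' @param trace A `gaze_trace`.
#' @param thresholds A [saccade_thresholds()].
#' @param task Task label; defaults to the trace attribute.
#' @return A list with `events` and, for prosaccade/antisaccade traces,
#'   `trials`.
#' @export
analyse_trace <- function(trace, thresholds = saccade_thresholds(),
                          task = NULL) {
  task <- task %||% attr(trace, "task") %||% "prosaccade"
  trace <- compute_velocity(trace)
  events <- detect_saccades(trace, thresholds)
  out <- list(events = events)
  if (task %in% c("prosaccade", "antisaccade")) {
    out$trials <- segment_trials(trace, events, task = task)
  }
  out
}
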