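# Shared fixtures and helpers; everything is generated in code.

noise_free_subject <- function(...) {
  subject_params(noise_sd_deg = 0, ...)
}

# Greedily match detected events to ground-truth events by onset proximity.
# Returns, for each ground-truth row, the index of the matching detected
# event or NA.
match_events <- function(detected, truth, tol_ms = 25) {
  vapply(truth$onset_ms, function(o) {
    if (nrow(detected) == 0) return(NA_integer_)
    d <- abs(detected$onset_ms - o)
    if (min(d) <= tol_ms) which.min(d) else NA_integer_
  }, integer(1))
}

# A minimal hand-built trace: constant-rate time base with a target step
# channel; the eye channel is irrelevant for trial segmentation tests.
step_trace <- function(step_times_ms, step_targets_deg, end_ms = 5000,
                       task = "prosaccade") {
  t <- 0:end_ms
  target <- numeric(length(t))
  for (i in seq_along(step_times_ms)) {
    target[t >= step_times_ms[i]] <- step_targets_deg[i]
  }
  as_gaze_trace(
    tibble::tibble(time_ms = t, eye_deg = 0, target_deg = target),
    sampling_rate_hz = 1000, task = task
  )
}

# Events table constructor for segmentation tests
events_tbl <- function(onset_ms, amplitude_deg, peak_velocity_dps = 300) {
  tibble::tibble(
    onset_ms = onset_ms,
    offset_ms = onset_ms + 50,
    amplitude_deg = amplitude_deg,
    peak_velocity_dps = peak_velocity_dps,
    peak_duration_s = abs(amplitude_deg) / peak_velocity_dps,
    direction = ifelse(amplitude_deg > 0, "right", "left")
  )
}
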