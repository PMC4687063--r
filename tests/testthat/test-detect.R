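flat_noisy_trace <- function(n, sd, seed) {
  set.seed(seed)
  as_gaze_trace(
    tibble::tibble(time_ms = 0:(n - 1), eye_deg = rnorm(n, 0, sd),
                   target_deg = 0),
    sampling_rate_hz = 1000
  )
}

test_that("noise-only traces produce no events at default thresholds", {
  expect_equal(nrow(detect_saccades(flat_noisy_trace(30000, 0.1, 1))), 0)
  expect_equal(nrow(detect_saccades(flat_noisy_trace(30000, 0.2, 2))), 0)
})

test_that("well-separated injected saccades are all recovered accurately", {
  subj <- subject_params(noise_sd_deg = 0.1)
  amps <- c(6, -8, 12, -20, 27)
  eye <- rep(0, 500); level <- 0
  onsets <- c()
  for (a in amps) {
    w <- simulate_saccade_waveform(a, subj)
    onsets <- c(onsets, length(eye))
    eye <- c(eye, level + w$position_deg, rep(level + a, 600))
    level <- level + a
  }
  set.seed(9)
  trace <- as_gaze_trace(
    tibble::tibble(time_ms = seq_along(eye) - 1,
                   eye_deg = eye + rnorm(length(eye), 0, 0.1),
                   target_deg = 0),
    sampling_rate_hz = 1000
  )
  det <- detect_saccades(trace)
  expect_equal(nrow(det), 5)
  expect_true(all(abs(det$onset_ms - onsets) <= 5))
  expect_true(all(abs(det$amplitude_deg - amps) < 0.2))
})

test_that("noise-free simulated sessions are recovered event for event", {
  subj <- noise_free_subject()
  s <- simulate_session(task_protocol("prosaccade", n_trials = 30), subj,
                        seed = 11)
  det <- detect_saccades(s$trace)
  expect_equal(nrow(det), nrow(s$events))
  m <- match_events(det, s$events)
  expect_false(any(is.na(m)))
  amp_err <- abs(det$amplitude_deg[m] - s$events$amplitude_deg)
  pv_err <- abs(det$peak_velocity_dps[m] - s$events$peak_velocity_dps) /
    s$events$peak_velocity_dps
  expect_true(all(amp_err < 0.1))
  expect_true(all(pv_err < 0.02))
})

test_that("detected events never overlap and onsets increase", {
  s <- simulate_session(task_protocol("selfpaced", duration_s = 15),
                        subject_params(), seed = 12)
  det <- detect_saccades(s$trace)
  expect_gt(nrow(det), 5)
  expect_true(all(diff(det$onset_ms) > 0))
  expect_true(all(det$onset_ms[-1] > det$offset_ms[-nrow(det)]))
  expect_true(all(det$offset_ms > det$onset_ms))
})

test_that("detection is invariant to a constant position offset", {
  s <- simulate_session(task_protocol("prosaccade", n_trials = 10),
                        subject_params(), seed = 13)
  d0 <- detect_saccades(s$trace)
  shifted <- s$trace
  shifted$eye_deg <- shifted$eye_deg + 12
  d1 <- detect_saccades(shifted)
  expect_equal(d0$onset_ms, d1$onset_ms)
  expect_equal(d0$amplitude_deg, d1$amplitude_deg, tolerance = 1e-9)
})

test_that("peak duration is amplitude over peak velocity by construction", {
  s <- simulate_session(task_protocol("prosaccade", n_trials = 10),
                        subject_params(), seed = 14)
  det <- detect_saccades(s$trace)
  expect_equal(det$peak_duration_s * det$peak_velocity_dps,
               abs(det$amplitude_deg), tolerance = 1e-12)
  expect_true(all((det$amplitude_deg > 0) == (det$direction == "right")))
})
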