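test_that("the same seed reproduces a session exactly", {
  subj <- subject_params()
  p <- task_protocol("prosaccade", n_trials = 10)
  s1 <- simulate_session(p, subj, seed = 42)
  s2 <- simulate_session(p, subj, seed = 42)
  expect_identical(s1$trace$eye_deg, s2$trace$eye_deg)
  expect_identical(s1$events, s2$events)
  expect_identical(s1$trials, s2$trials)
  s3 <- simulate_session(p, subj, seed = 43)
  expect_false(identical(s1$trace$eye_deg, s3$trace$eye_deg))
})

test_that("prosaccade sessions present 60 jumps between 5 and 30 deg", {
  s <- simulate_session(task_protocol("prosaccade"), subject_params(),
                        seed = 1)
  expect_equal(nrow(s$trials), 60)
  mag <- abs(s$trials$step_amplitude_deg)
  expect_true(all(mag >= 5 & mag <= 30))
  # target step channel in the trace shows the same 60 steps
  steps <- which(abs(diff(s$trace$target_deg)) > 0.5)
  expect_equal(length(steps), 60)
})

test_that("prosaccade target direction runs never exceed four", {
  for (sd in 1:5) {
    s <- simulate_session(task_protocol("prosaccade"), subject_params(),
                          seed = 100 + sd, trace = FALSE)
    r <- rle(sign(s$trials$step_amplitude_deg))
    expect_lte(max(r$lengths), 4)
  }
})

test_that("noise-free generated peak velocities lie exactly on the main sequence", {
  subj <- noise_free_subject(vmax = 480, k = 7)
  s <- simulate_session(task_protocol("prosaccade"), subj, seed = 3,
                        trace = FALSE)
  expect_equal(
    s$events$peak_velocity_dps,
    subj$vmax * (1 - exp(-abs(s$events$amplitude_deg) / subj$k)),
    tolerance = 1e-12
  )
})

test_that("degenerate antisaccade error probabilities behave as stated", {
  p <- task_protocol("antisaccade")
  all_err <- simulate_session(p, subject_params(antisaccade_error_prob = 1),
                              seed = 5, trace = FALSE)
  expect_equal(nrow(all_err$trials), 39)
  expect_true(all(all_err$trials$is_error))
  # errors go toward the target: response sign equals step sign
  expect_true(all(sign(all_err$trials$response_amplitude_deg) ==
                    sign(all_err$trials$step_amplitude_deg)))
  no_err <- simulate_session(p, subject_params(antisaccade_error_prob = 0),
                             seed = 6, trace = FALSE)
  expect_false(any(no_err$trials$is_error))
  expect_true(all(sign(no_err$trials$response_amplitude_deg) ==
                    -sign(no_err$trials$step_amplitude_deg)))
})

test_that("near-deterministic self-paced pacing yields ~60 refixations in 30 s", {
  subj <- subject_params(selfpaced_isi_mean_s = 0.5,
                         selfpaced_isi_shape = 1e6)
  s <- simulate_session(task_protocol("selfpaced"), subj, seed = 7,
                        trace = FALSE)
  n30 <- sum(s$events$onset_ms <= 30000)
  expect_gte(n30, 59)
  expect_lte(n30, 61)
})

test_that("simulated antisaccade error counts are binomial", {
  p <- task_protocol("antisaccade")
  subj <- subject_params(antisaccade_error_prob = 0.7)
  errs <- 0L; n <- 0L
  for (r in 1:260) {
    s <- simulate_session(p, subj, seed = 10000 + r, trace = FALSE)
    errs <- errs + sum(s$trials$is_error)
    n <- n + nrow(s$trials)
  }
  expect_gte(n, 10000)
  se <- sqrt(0.7 * 0.3 / n)
  expect_lt(abs(errs / n - 0.7), 3 * se)
})

test_that("self-paced ground-truth ISIs recover the configured gamma mean", {
  subj <- subject_params(selfpaced_isi_mean_s = 0.8, selfpaced_isi_shape = 8)
  isis <- c()
  for (r in 1:300) {
    s <- simulate_session(task_protocol("selfpaced"), subj,
                          seed = 20000 + r, trace = FALSE)
    isis <- c(isis, diff(s$events$onset_ms) / 1000)
  }
  se <- (0.8 / sqrt(8)) / sqrt(length(isis))
  expect_lt(abs(mean(isis) - 0.8), 3 * se)
})
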