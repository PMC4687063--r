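test_that("latency is saccade onset minus step time", {
  trace <- step_trace(1000, 10, end_ms = 3000)
  ev <- events_tbl(1180, 9)
  tr <- segment_trials(trace, ev)
  expect_equal(tr$latency_ms, 180)
  expect_equal(tr$exclusion_reason, "none")
  expect_equal(tr$gain, 0.9)
})

test_that("responses faster than 80 ms are anticipatory", {
  trace <- step_trace(1000, 10, end_ms = 3000)
  tr <- segment_trials(trace, events_tbl(1060, 9))
  expect_equal(tr$exclusion_reason, "anticipatory")
  expect_true(is.na(tr$gain))
})

test_that("steps without a qualifying saccade are no_response", {
  trace <- step_trace(1000, 10, end_ms = 3000)
  # only a tiny saccade inside the window, and a big one far outside it
  ev <- events_tbl(c(1200, 2500), c(0.5, 9))
  tr <- segment_trials(trace, ev)
  expect_equal(tr$exclusion_reason, "no_response")
  expect_true(is.na(tr$latency_ms))
})

test_that("gain follows the signed-ratio convention", {
  expect_equal(compute_gain(10, 10), 1.0)
  expect_equal(compute_gain(8, 10), 0.8)
  expect_equal(compute_gain(-9, -10), 0.9)
  expect_error(compute_gain(5, 0), class = "sacclong_invalid_argument")
})

test_that("antisaccade responses toward the target are direction errors", {
  trace <- step_trace(c(1000, 2000), c(10, 0), end_ms = 4000,
                      task = "antisaccade")
  # response goes +6 toward the +10 target: an error
  tr <- segment_trials(trace, events_tbl(1250, 6), task = "antisaccade")
  expect_equal(nrow(tr), 1)   # the return-to-zero step is not a trial
  expect_false(tr$response_direction_correct)
  # mirror-direction response is correct
  tr2 <- segment_trials(trace, events_tbl(1250, -6), task = "antisaccade")
  expect_true(tr2$response_direction_correct)
})

test_that("a trace without target steps cannot be segmented", {
  trace <- step_trace(numeric(0), numeric(0), end_ms = 2000)
  expect_error(segment_trials(trace, events_tbl(500, 5)),
               class = "sacclong_invalid_input")
})

test_that("segmented simulated sessions match their ground truth", {
  subj <- noise_free_subject()
  s <- simulate_session(task_protocol("prosaccade", n_trials = 20), subj,
                        seed = 21)
  a <- analyse_trace(s$trace)
  scored <- a$trials[a$trials$exclusion_reason == "none", ]
  expect_equal(nrow(a$trials), 20)
  expect_equal(scored$latency_ms, s$trials$latency_ms[scored$trial],
               tolerance = 0.05)
  expect_equal(scored$gain, s$trials$gain[scored$trial], tolerance = 0.02)
})
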