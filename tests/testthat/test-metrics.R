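test_that("HSEM-alpha matches the two-point slope", {
  ev <- tibble::tibble(amplitude_deg = c(10, 20),
                       peak_duration_s = c(0.025, 0.045))
  h <- compute_hsem_alpha(ev, min_n = 2)
  expect_equal(h$hsem_alpha, 0.002, tolerance = 1e-12)
})

test_that("HSEM-alpha equals 1/vmax when peak velocity is saturated", {
  a <- seq(20, 30, length.out = 15)
  ev <- tibble::tibble(amplitude_deg = a, peak_velocity_dps = 500)
  h <- suppressWarnings(compute_hsem_alpha(ev))
  expect_equal(h$hsem_alpha, 1 / 500, tolerance = 1e-12)
  expect_equal(h$intercept_s, 0, tolerance = 1e-12)
})

test_that("HSEM-alpha matches an independent least-squares computation", {
  # closed-form OLS slope via moments, independent of lm()
  a <- seq(15, 30, length.out = 60)
  pd <- a / main_sequence_velocity(a, 500, 8)
  slope_oracle <- sum((a - mean(a)) * (pd - mean(pd))) / sum((a - mean(a))^2)
  h <- compute_hsem_alpha(tibble::tibble(amplitude_deg = a,
                                         peak_duration_s = pd))
  expect_equal(h$hsem_alpha, slope_oracle, tolerance = 1e-12)
  # over 15-30 deg the slope times vmax sits close below 1: the
  # inverse-Vmax correspondence is asymptotic, not exact
  expect_gt(h$hsem_alpha * 500, 0.84)
  expect_lt(h$hsem_alpha * 500, 0.92)
})

test_that("degenerate HSEM designs are flagged", {
  ev <- tibble::tibble(amplitude_deg = rep(10, 12),
                       peak_velocity_dps = rep(350, 12))
  expect_false(compute_hsem_alpha(ev)$defined)
})

test_that("antisaccade error rate is the percentage of toward-target trials", {
  tr <- tibble::tibble(
    response_direction_correct = c(rep(FALSE, 4), rep(TRUE, 6)),
    exclusion_reason = "none"
  )
  expect_equal(antisaccade_error_rate(tr)$error_pct, 40)
  # invariant under reordering
  set.seed(41)
  expect_equal(antisaccade_error_rate(tr[sample(10), ])$error_pct, 40)
  # no_response trials leave the denominator
  tr2 <- dplyr::bind_rows(tr, tibble::tibble(
    response_direction_correct = NA, exclusion_reason = "no_response"))
  expect_equal(antisaccade_error_rate(tr2)$error_pct, 40)
  expect_warning(
    out <- antisaccade_error_rate(
      tibble::tibble(response_direction_correct = logical(0),
                     exclusion_reason = character(0))),
    "no scoreable"
  )
  expect_true(is.na(out$error_pct))
})

test_that("error rate from an error-free simulation is zero", {
  s <- simulate_session(task_protocol("antisaccade"),
                        subject_params(antisaccade_error_prob = 0), seed = 44)
  a <- analyse_trace(s$trace)
  expect_equal(antisaccade_error_rate(a$trials)$error_pct, 0)
})

test_that("self-paced summary counts regular refixations", {
  ev <- events_tbl(seq(500, 30000, by = 500), rep(c(17, -17), 30)[1:60])
  sp <- selfpaced_summary(ev)
  expect_equal(sp$count, 60)
  expect_true(all(abs(sp$isi_s - 0.5) < 1e-9))
  # empty input
  sp0 <- selfpaced_summary(events_tbl(numeric(0), numeric(0)))
  expect_equal(sp0$count, 0)
  expect_length(sp0$isi_s, 0)
})

test_that("widening the self-paced window never decreases the count", {
  s <- simulate_session(task_protocol("selfpaced"), subject_params(),
                        seed = 45)
  a <- analyse_trace(s$trace)
  counts <- vapply(c(5, 10, 20, 30), function(w) {
    selfpaced_summary(a$events, window_s = w)$count
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("session_metrics assembles all per-visit summaries", {
  subj <- subject_params()
  pro <- analyse_trace(simulate_session(task_protocol("prosaccade"),
                                        subj, seed = 46)$trace)
  ant <- analyse_trace(simulate_session(task_protocol("antisaccade"),
                                        subj, seed = 47)$trace)
  sp <- analyse_trace(simulate_session(task_protocol("selfpaced"),
                                       subj, seed = 48)$trace)
  sm <- session_metrics(prosaccade = pro, antisaccade = ant, selfpaced = sp)
  expect_equal(nrow(sm), 1)
  expect_false(any(is.na(c(sm$vmax_dps, sm$gain, sm$latency_ms,
                           sm$antisaccade_error_pct, sm$hsem_alpha))))
  expect_gt(sm$selfpaced_count, 10)
  expect_gt(length(sm$isi_s[[1]]), 5)
  # a missing task leaves NA summaries
  sm2 <- session_metrics(prosaccade = pro)
  expect_true(is.na(sm2$antisaccade_error_pct))
  expect_true(is.na(sm2$selfpaced_count))
})
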