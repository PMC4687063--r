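test_that("the default cohort has 9 patients, 8 treated, 1 never treated", {
  coh <- simulate_cohort(cohort_config(seed = 1))
  m <- coh$manifest
  expect_equal(length(unique(m$patient_id)), 9)
  ever_treated <- unique(m$patient_id[m$group == "treated"])
  expect_equal(length(ever_treated), 8)
  expect_equal(setdiff(1:9, ever_treated), 5)
  # patients 1 and 2 carry pre-treatment visits, labelled untreated
  for (pid in 1:2) {
    pre <- m[m$patient_id == pid & m$months_since_onset < 0, ]
    expect_equal(nrow(pre), 2)
    expect_true(all(pre$group == "untreated"))
  }
})

test_that("visit intervals and follow-up lengths respect the configured ranges", {
  for (sd in 1:4) {
    coh <- simulate_cohort(cohort_config(seed = 200 + sd))
    m <- coh$manifest
    for (pid in unique(m$patient_id)) {
      mo <- sort(m$months_since_onset[m$patient_id == pid])
      if (all(is.na(mo))) mo <- sort(m$months[m$patient_id == pid])
      gaps <- diff(mo)
      expect_true(all(gaps >= 7 - 1e-9 & gaps <= 12 + 1e-9))
      expect_lte(max(mo[mo >= 0]), 61)
    }
  }
})

test_that("a degenerate generator yields constant per-visit parameters", {
  cfg <- cohort_config(
    treated_slopes = list(isi_s = 0, gain = 0, latency_ms = 0),
    untreated_slopes = list(isi_s = 0, gain = 0, latency_ms = 0),
    random_intercept_sd = list(isi_s = 0, gain = 0, latency_ms = 0),
    seed = 2
  )
  coh <- simulate_cohort(cfg)
  vp <- dplyr::left_join(coh$manifest, coh$visit_params, by = "session_id")
  for (pid in unique(vp$patient_id)) {
    p <- vp[vp$patient_id == pid, ]
    expect_equal(length(unique(p$selfpaced_isi_mean_s)), 1)
    expect_equal(length(unique(p$gain_mean)), 1)
    expect_equal(length(unique(p$latency_mean_ms)), 1)
  }
})

test_that("metric means drift linearly at the group slope", {
  cfg <- cohort_config(
    n_patients = 2, n_treated = 2, n_pretreatment_patients = 0,
    followup_months_range = c(48, 48),
    treated_slopes = list(isi_s = -0.001),
    untreated_slopes = list(isi_s = 0.026),
    random_intercept_sd = list(isi_s = 0),
    seed = 3
  )
  coh <- simulate_cohort(cfg)
  vp <- dplyr::left_join(coh$manifest, coh$visit_params, by = "session_id")
  base <- cfg$baseline_subject$selfpaced_isi_mean_s
  expect_equal(vp$selfpaced_isi_mean_s, base - 0.001 * vp$months,
               tolerance = 1e-12)
  # 48 months of treated drift lower the mean ISI by 0.048 s
  last <- vp[which.max(vp$months), ]
  expect_gte(last$months, 40)
  expect_equal(base - last$selfpaced_isi_mean_s, 0.001 * last$months,
               tolerance = 1e-12)
})

test_that("cohorts are reproducible and reject unknown metric names", {
  c1 <- simulate_cohort(cohort_config(seed = 4), level = "trials")
  c2 <- simulate_cohort(cohort_config(seed = 4), level = "trials")
  expect_identical(c1$manifest, c2$manifest)
  expect_identical(c1$trials, c2$trials)
  expect_error(cohort_config(treated_slopes = list(bogus = 1)),
               class = "sacclong_invalid_argument")
})

test_that("trial-level draws carry every analysed metric per visit", {
  coh <- simulate_cohort(cohort_config(seed = 5), level = "trials")
  tr <- coh$trials
  expect_setequal(unique(tr$metric), c("isi_s", "gain", "latency_ms"))
  counts <- dplyr::count(tr, session_id, metric)
  expect_true(all(counts$n >= 3))
  expect_setequal(unique(tr$session_id), coh$manifest$session_id)
})
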