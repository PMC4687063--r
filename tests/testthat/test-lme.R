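perfect_data <- function(slope, intercepts, months = seq(0, 50, by = 10),
                         group = "treated") {
  purrr::map_dfr(seq_along(intercepts), function(i) {
    tibble::tibble(patient_id = i, months = months, group = group,
                   value = intercepts[i] + slope * months)
  })
}

test_that("noise-free linear data recover the slope to numerical precision", {
  d <- dplyr::bind_rows(
    perfect_data(0.01, c(1, 1.2, 0.9), group = "treated"),
    perfect_data(-0.02, c(1.1, 1.05), group = "untreated")
  )
  fit <- suppressWarnings(fit_saccade_lme(d, metric = "demo"))
  cc <- tidy(fit)
  expect_equal(cc$coefficient[cc$group == "treated"], 0.01,
               tolerance = 1e-8)
  expect_equal(cc$coefficient[cc$group == "untreated"], -0.02,
               tolerance = 1e-8)
  expect_equal(cc$coefficient[cc$group == "interaction"], 0.03,
               tolerance = 1e-8)
})

test_that("adding a constant shifts intercepts but never slopes", {
  set.seed(51)
  coh <- simulate_cohort(cohort_config(seed = 51), level = "trials")
  f0 <- fit_saccade_lme(coh$trials, metric = "isi_s")
  shifted <- coh$trials
  shifted$value[shifted$metric == "isi_s"] <-
    shifted$value[shifted$metric == "isi_s"] + 5
  f1 <- fit_saccade_lme(shifted, metric = "isi_s")
  expect_equal(tidy(f0)$coefficient, tidy(f1)$coefficient, tolerance = 1e-6)
})

test_that("slope estimates are unbiased over simulated cohorts", {
  ests <- numeric(120)
  for (r in seq_along(ests)) {
    coh <- simulate_cohort(cohort_config(seed = 60000 + r), level = "trials")
    cc <- tidy(fit_saccade_lme(coh$trials, metric = "gain"))
    ests[r] <- cc$coefficient[cc$group == "treated"]
  }
  mc_se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - 0.001), 2 * mc_se)
})

test_that("a single-patient group is flagged with no coefficient", {
  d <- dplyr::bind_rows(
    perfect_data(0.01, c(1, 1.2), group = "treated"),
    perfect_data(0.02, 1.1, group = "untreated")
  )
  d$value <- d$value + rnorm(nrow(d), 0, 0.01)
  cc <- suppressWarnings(tidy(fit_saccade_lme(d, metric = "demo")))
  un <- cc[cc$group == "untreated", ]
  expect_equal(un$flag, "single_patient")
  expect_true(is.na(un$coefficient))
})

test_that("tidy and glance expose the model metadata", {
  coh <- simulate_cohort(cohort_config(seed = 52), level = "trials")
  fit <- fit_saccade_lme(coh$trials, metric = "latency_ms")
  cc <- tidy(fit)
  expect_setequal(cc$group, c("treated", "untreated", "interaction"))
  expect_true(all(cc$se[cc$flag %in% c("ok", "singular")] > 0))
  expect_true(all(cc$n_patients >= 2))
  g <- glance(fit)
  expect_equal(g$metric, "latency_ms")
  expect_match(g$p_method, "Wald")
  expect_s3_class(autoplot(fit), "ggplot")
})
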