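cs <- function(metric, values, months = seq(0, by = 12,
                                            length.out = length(values))) {
  change_from_baseline(tibble::tibble(
    patient_id = 1, months = months, metric = metric, value = values
  ))
}

test_that("change scores are proportional changes with metric-specific orientation", {
  g <- cs("gain", c(0.8, 0.9))
  expect_equal(g$value, c(0, 0.125))
  expect_identical(g$improvement, c(FALSE, TRUE))
  h <- cs("hsem_alpha", c(0.004, 0.003))
  expect_equal(h$value[2], -0.25)
  expect_true(h$improvement[2])      # decrease is improvement for HSEM-alpha
  l <- cs("latency_ms", c(250, 300))
  expect_false(l$improvement[2])     # latency increase is deterioration
})

test_that("the baseline visit scores exactly zero and is no improvement", {
  x <- cs("gain", c(0.8, 0.8))
  expect_equal(x$value[2], 0)
  expect_false(x$improvement[2])
})

test_that("a zero or missing baseline is flagged, not computed", {
  z <- cs("gain", c(0, 0.5))
  expect_true(all(z$flag == "no_baseline"))
  expect_true(all(is.na(z$value)))
})

test_that("change scores are scale invariant", {
  v <- c(0.8, 0.9, 0.7, 1.0)
  expect_equal(cs("gain", v)$value, cs("gain", v * 3.7)$value,
               tolerance = 1e-12)
})

test_that("the baseline is the first visit at or after month zero", {
  d <- tibble::tibble(patient_id = 1, months = c(-19, -9, 0, 11),
                      metric = "gain", value = c(1.0, 0.95, 0.8, 0.9))
  out <- change_from_baseline(d)
  expect_equal(out$value[out$months == 0], 0)
  expect_equal(out$value[out$months == 11], 0.125)
  # pre-treatment visits are scored relative to the month-zero baseline
  expect_equal(out$value[out$months == -19], 0.25)
})

test_that("multiple patients and metrics are scored independently", {
  d <- tibble::tibble(
    patient_id = rep(1:2, each = 4),
    months = rep(c(0, 10, 20, 30), 2),
    metric = "isi_s",
    value = c(0.8, 0.8, 0.9, 1.0, 1.0, 0.9, 0.8, 0.7)
  )
  out <- change_from_baseline(d)
  expect_equal(out$value[out$patient_id == 2],
               c(0, -0.1, -0.2, -0.3))
  expect_true(all(out$improvement[out$patient_id == 2][-1]))
})
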