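#' Fit the peak-velocity main sequence
#'
#' Nonlinear least-squares fit of the saturating exponential
#' `V = vmax * (1 - exp(-A / k))` to (amplitude, peak velocity) pairs, where
#' `vmax` is the asymptotic peak velocity (deg/s) and `k` the amplitude
#' constant (deg). Initialised at the maximum observed peak velocity and
#' `k = 10` deg, with bounds `vmax` in (0, 2000] and `k` in (0, 100];
#' a Levenberg-Marquardt refit from a perturbed start is attempted if the
#' first fit fails.
#'
#' @param events Detected (or ground-truth) saccades: a data frame with
#'   `amplitude_deg` and `peak_velocity_dps` columns; amplitudes are used in
#'   absolute value.
#' @param min_n Minimum number of saccades for an identifiable fit.
#'
#' @return An object of class `main_sequence_fit` with fields `vmax`, `k`,
#'   `residual_sd`, `n_saccades`, `converged`, plus the fitted `nls` object
#'   (`fit`) and the data used. When the design is non-identifiable (too few
#'   saccades or a single distinct amplitude) `converged` is `FALSE` and the
#'   estimates are `NA`.
#' @seealso [tidy.main_sequence_fit()], [autoplot.main_sequence_fit()]
#' @export
#' @examples
#' a <- seq(5, 30, length.out = 20)
#' ev <- tibble::tibble(amplitude_deg = a,
#'                      peak_velocity_dps = main_sequence_velocity(a, 500, 8))
#' fit_main_sequence(ev, min_n = 10)
fit_main_sequence <- function(events, min_n = 10) {
  dat <- tibble(
    amplitude_deg = abs(events$amplitude_deg),
    peak_velocity_dps = events$peak_velocity_dps
  )
  dat <- dat[stats::complete.cases(dat), ]
  failed <- function(reason) {
    structure(list(vmax = NA_real_, k = NA_real_, residual_sd = NA_real_,
                   n_saccades = nrow(dat), converged = FALSE,
                   reason = reason, fit = NULL, data = dat),
              class = "main_sequence_fit")
  }
  if (nrow(dat) < min_n) return(failed("fewer saccades than `min_n`"))
  if (length(unique(round(dat$amplitude_deg, 6))) < 2) {
    return(failed("a single distinct amplitude is non-identifiable"))
  }

  start <- list(vmax = max(dat$peak_velocity_dps), k = 10)
  fit <- try_main_sequence_nls(dat, start)
  if (is.null(fit)) {
    fit <- try_main_sequence_nls(dat, list(vmax = 1.5 * start$vmax, k = 25))
  }
  if (is.null(fit)) return(failed("optimizer failed to converge"))

  est <- coef(fit)
  if (any(!is.finite(est)) || any(est <= 0)) {
    return(failed("non-positive parameter estimate"))
  }
  structure(
    list(vmax = unname(est["vmax"]), k = unname(est["k"]),
         residual_sd = sqrt(sum(residuals(fit)^2) / max(1, nrow(dat) - 2)),
         n_saccades = nrow(dat), converged = TRUE, reason = NULL,
         fit = fit, data = dat),
    class = "main_sequence_fit"
  )
}

try_main_sequence_nls <- function(dat, start) {
  out <- tryCatch(
    minpack.lm::nlsLM(
      peak_velocity_dps ~ vmax * (1 - exp(-amplitude_deg / k)),
      data = dat, start = start,
      lower = c(vmax = 1e-6, k = 1e-6), upper = c(vmax = 2000, k = 100),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL, warning = function(w) NULL
  )
  out
}

#' @export
print.main_sequence_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("<main_sequence_fit> vmax = %.1f deg/s, k = %.2f deg (n = %d, residual SD = %.1f)\n",
                x$vmax, x$k, x$n_saccades, x$residual_sd))
  } else {
    cat("<main_sequence_fit> not converged:", x$reason, "\n")
  }
  invisible(x)
}

#' Tidy a main-sequence fit
#'
#' @param x A `main_sequence_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`vmax`, `k`): estimate,
#'   standard error, statistic and p value from the nonlinear fit.
#' @method tidy main_sequence_fit
#' @export
tidy.main_sequence_fit <- function(x, ...) {
  if (!x$converged) {
    return(tibble(term = c("vmax", "k"), estimate = NA_real_,
                  std.error = NA_real_, statistic = NA_real_,
                  p.value = NA_real_))
  }
  s <- summary(x$fit)$coefficients
  tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
         statistic = s[, 3], p.value = s[, 4])
}

#' Glance at a main-sequence fit
#'
#' @param x A `main_sequence_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `vmax`, `k`, `residual_sd`, `n_saccades`,
#'   `converged`.
#' @method glance main_sequence_fit
#' @export
glance.main_sequence_fit <- function(x, ...) {
  tibble(vmax = x$vmax, k = x$k, residual_sd = x$residual_sd,
         n_saccades = x$n_saccades, converged = x$converged)
}

#' Plot a main-sequence fit
#'
#' Scatter of peak velocity against amplitude with the fitted saturating
#' exponential overlaid.
#'
#' @param object A `main_sequence_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot main_sequence_fit
#' @export
autoplot.main_sequence_fit <- function(object, ...) {
  p <- ggplot2::ggplot(object$data,
                       ggplot2::aes(x = .data$amplitude_deg,
                                    y = .data$peak_velocity_dps)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "amplitude (deg)", y = "peak velocity (deg/s)",
                  title = "Main sequence")
  if (object$converged) {
    grid <- tibble(amplitude_deg = seq(0, max(object$data$amplitude_deg),
                                       length.out = 200))
    grid$peak_velocity_dps <- main_sequence_velocity(grid$amplitude_deg,
                                                     object$vmax, object$k)
    p <- p + ggplot2::geom_line(data = grid, colour = "red") +
      ggplot2::labs(subtitle = sprintf("vmax = %.0f deg/s, k = %.1f deg",
                                       object$vmax, object$k))
  }
  p
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
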