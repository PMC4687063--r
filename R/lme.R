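#' Linear mixed-effects trajectory models by treatment group
#'
#' Fits the longitudinal models used to compare treated and untreated
#' trajectories of a metric: (i) one model per group,
#' `value ~ months + (1 | patient)`, whose `months` coefficient is the
#' group's per-month slope; and (ii) a combined model
#' `value ~ months * group + (1 | patient)` whose interaction term tests
#' whether the two slopes differ. Only the intercept varies across
#' patients; random slopes are deliberately out of scope. Months are
#' counted since treatment onset for treated observations and since first
#' visit for untreated ones.
#'
#' p values are Wald tests, `t = estimate / SE` against a t distribution
#' with residual degrees of freedom (`n_obs` minus the number of fixed
#' effects); with the trial-level row counts used here this is effectively
#' a z test. The method is recorded in the result.
#'
#' @param data Long-format trial-level (or session-level) observations with
#'   columns `patient_id`, `months`, `group` (`"treated"`/`"untreated"`)
#'   and `value`; typically one row per trial.
#' @param metric Metric name carried into the output (and used to subset
#'   when `data` has a `metric` column).
#'
#' @return An object of class `saccade_lme`: a list with `coefficients` (a
#'   tibble with one row per term: `metric`, `group` = treated / untreated /
#'   interaction, `coefficient` per month, `se`, `t`, `p`,
#'   `random_intercept_sd`, `n_obs`, `n_patients`, `flag`), `models` (the
#'   underlying `lmerMod` objects), `metric` and `p_method`. Groups with
#'   fewer than two patients, singular or non-converged fits are flagged and
#'   report no coefficient.
#' @seealso [tidy.saccade_lme()], [glance.saccade_lme()],
#'   [autoplot.saccade_lme()]
#' @export
#' @examples
#' coh <- simulate_cohort(cohort_config(seed = 7), level = "trials")
#' fit <- fit_saccade_lme(coh$trials, metric = "isi_s")
#' tidy(fit)
fit_saccade_lme <- function(data, metric = NULL) {
  if (!is.null(metric) && "metric" %in% names(data)) {
    data <- data[data$metric == metric, ]
  }
  metric <- metric %||% "value"
  needed <- c("patient_id", "months", "group", "value")
  stopifnot_msg(all(needed %in% names(data)),
                msg = paste("`data` must have columns",
                            paste(needed, collapse = ", ")))
  data <- data[stats::complete.cases(data[needed]), ]
  stopifnot_msg(nrow(data) > 0, msg = "no observations to fit")
  if (length(unique(data$months)) < 3) {
    warn("fewer than 3 distinct time points; slopes are weakly identified")
  }

  rows <- list(); models <- list()
  for (grp in c("treated", "untreated")) {
    gd <- data[data$group == grp, ]
    rows[[grp]] <- lme_group_row(gd, grp, metric)
    models[[grp]] <- attr(rows[[grp]], "model")
  }
  inter <- lme_interaction_row(data, metric)
  models$combined <- attr(inter, "model")
  coefs <- bind_rows(rows$treated, rows$untreated, inter)

  structure(list(coefficients = coefs, models = models, metric = metric,
                 p_method = "Wald t, residual df (n_obs - n_fixed)",
                 data = data),
            class = "saccade_lme")
}

lme_na_row <- function(metric, grp, gd, flag) {
  r <- tibble(metric = metric, group = grp, coefficient = NA_real_,
              se = NA_real_, t = NA_real_, p = NA_real_,
              random_intercept_sd = NA_real_,
              n_obs = nrow(gd),
              n_patients = length(unique(gd$patient_id)),
              flag = flag)
  attr(r, "model") <- NULL
  r
}

lme_group_row <- function(gd, grp, metric) {
  n_pat <- length(unique(gd$patient_id))
  if (nrow(gd) == 0) return(lme_na_row(metric, grp, gd, "no_data"))
  if (n_pat < 2) return(lme_na_row(metric, grp, gd, "single_patient"))
  m <- tryCatch(
    suppressMessages(
      lme4::lmer(value ~ months + (1 | patient_id), data = gd, REML = TRUE)
    ),
    error = function(e) NULL
  )
  if (is.null(m)) return(lme_na_row(metric, grp, gd, "fit_failed"))
  flag <- if (lme4::isSingular(m)) "singular" else "ok"
  r <- wald_row(m, "months", metric, grp, gd)
  r$flag <- flag
  attr(r, "model") <- m
  r
}

lme_interaction_row <- function(data, metric) {
  n_pat <- length(unique(data$patient_id))
  if (length(unique(data$group)) < 2 || n_pat < 2) {
    return(lme_na_row(metric, "interaction", data, "one_group"))
  }
  data$group <- factor(data$group, levels = c("untreated", "treated"))
  m <- tryCatch(
    suppressMessages(
      lme4::lmer(value ~ months * group + (1 | patient_id), data = data,
                 REML = TRUE)
    ),
    error = function(e) NULL
  )
  if (is.null(m)) return(lme_na_row(metric, "interaction", data, "fit_failed"))
  flag <- if (lme4::isSingular(m)) "singular" else "ok"
  r <- wald_row(m, "months:grouptreated", metric, "interaction", data)
  r$flag <- flag
  attr(r, "model") <- m
  r
}

wald_row <- function(m, term, metric, grp, gd) {
  fe <- lme4::fixef(m)
  se <- sqrt(diag(as.matrix(vcov(m))))
  est <- unname(fe[term]); s <- unname(se[names(fe) == term])
  df <- stats::nobs(m) - length(fe)
  tval <- est / s
  tibble(
    metric = metric, group = grp,
    coefficient = est, se = s, t = tval,
    p = 2 * pt(-abs(tval), df = df),
    random_intercept_sd =
      sqrt(unname(lme4::VarCorr(m)$patient_id[1, 1])),
    n_obs = stats::nobs(m),
    n_patients = length(unique(gd$patient_id)),
    flag = "ok"
  )
}

#' @export
print.saccade_lme <- function(x, ...) {
  cat("<saccade_lme> metric:", x$metric, "| p:", x$p_method, "\n")
  print(x$coefficients)
  invisible(x)
}

#' Tidy a longitudinal mixed-model fit
#'
#' @param x A `saccade_lme`.
#' @param ... Unused.
#' @return The coefficient tibble: one row for the treated slope, the
#'   untreated slope and the months-by-group interaction.
#' @method tidy saccade_lme
#' @export
tidy.saccade_lme <- function(x, ...) x$coefficients

#' Glance at a longitudinal mixed-model fit
#'
#' @param x A `saccade_lme`.
#' @param ... Unused.
#' @return A one-row tibble: metric, total observations and patients, the
#'   interaction p value and the p-value method.
#' @method glance saccade_lme
#' @export
glance.saccade_lme <- function(x, ...) {
  cc <- x$coefficients
  tibble(
    metric = x$metric,
    n_obs = sum(cc$n_obs[cc$group != "interaction"], na.rm = TRUE),
    n_patients = length(unique(x$data$patient_id)),
    interaction_p = cc$p[cc$group == "interaction"][1],
    p_method = x$p_method
  )
}

#' Plot fitted group trajectories
#'
#' Per-patient observations (visit means when trial-level rows are given)
#' against months, with the fitted group-level slopes overlaid.
#'
#' @param object A `saccade_lme`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot saccade_lme
#' @export
autoplot.saccade_lme <- function(object, ...) {
  d <- object$data |>
    group_by(.data$patient_id, .data$months, .data$group) |>
    summarise(value = mean(.data$value), .groups = "drop")
  cc <- object$coefficients
  fits <- list()
  for (grp in c("treated", "untreated")) {
    m <- object$models[[grp]]
    if (is.null(m)) next
    gd <- d[d$group == grp, ]
    grid <- tibble(months = seq(min(gd$months), max(gd$months),
                                length.out = 50))
    fe <- lme4::fixef(m)
    grid$value <- fe[1] + fe["months"] * grid$months
    grid$group <- grp
    fits[[grp]] <- grid
  }
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$months, y = .data$value,
                                       colour = .data$group)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$patient_id), alpha = 0.4) +
    ggplot2::geom_point(size = 1.5, alpha = 0.7) +
    ggplot2::labs(x = "months", y = object$metric, colour = "group")
  if (length(fits) > 0) {
    p <- p + ggplot2::geom_line(data = bind_rows(fits), linewidth = 1.1)
  }
  p
}
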