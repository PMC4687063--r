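#' Proportional change from baseline
#'
#' For each patient and metric, expresses every visit's value as the change
#' from the baseline value as a proportion of that baseline:
#' `(value - baseline) / baseline`. The baseline visit is the first visit at
#' or after month zero when one exists (i.e. the first on-treatment visit
#' for treated patients), otherwise the earliest visit. Whether a change
#' counts as improvement is metric-specific (see [metric_orientation()]):
#' positive changes are improvements for gain, Vmax and self-paced count;
#' negative changes are improvements for HSEM-alpha, latency, antisaccade
#' error rate and ISI.
#'
#' @param data Long-format per-visit metric values: a data frame with
#'   columns `patient_id`, `months`, `metric`, `value` (one row per visit
#'   and metric).
#' @param orientation Named character vector mapping metric names to
#'   `"increase"` or `"decrease"` (the direction that is an improvement).
#'
#' @return A tibble with one row per visit and metric: `patient_id`,
#'   `months`, `metric`, `value` (the proportional change, 0 at baseline),
#'   `improvement` (logical; `FALSE` for a zero change) and `flag`
#'   (`"ok"`, or `"no_baseline"` when the baseline is missing or zero, in
#'   which case `value` is `NA`).
#' @export
#' @examples
#' d <- tibble::tibble(patient_id = 1, months = c(0, 12),
#'                     metric = "gain", value = c(0.8, 0.9))
#' change_from_baseline(d)
change_from_baseline <- function(data, orientation = metric_orientation()) {
  needed <- c("patient_id", "months", "metric", "value")
  stopifnot_msg(all(needed %in% names(data)),
                msg = paste("`data` must have columns",
                            paste(needed, collapse = ", ")))
  data |>
    group_by(.data$patient_id, .data$metric) |>
    arrange(.data$months, .by_group = TRUE) |>
    mutate(
      .base = baseline_value(.data$months, .data$value),
      flag = ifelse(is.na(.data$.base) | .data$.base == 0,
                    "no_baseline", "ok"),
      change = ifelse(.data$flag == "ok",
                      (.data$value - .data$.base) / .data$.base, NA_real_)
    ) |>
    ungroup() |>
    mutate(
      improvement = improvement_flag(.data$change, .data$metric, orientation)
    ) |>
    select("patient_id", "months", "metric", value = "change",
           "improvement", "flag")
}

baseline_value <- function(months, value) {
  i <- which(months >= 0 & !is.na(value))
  if (length(i) == 0) i <- which(!is.na(value))
  if (length(i) == 0) return(NA_real_)
  value[i[which.min(months[i])]]
}

improvement_flag <- function(change, metric, orientation) {
  dir <- unname(orientation[metric])
  out <- ifelse(dir == "increase", change > 0,
                ifelse(dir == "decrease", change < 0, NA))
  out[is.na(change)] <- NA
  out
}

#' Plot change-from-baseline trajectories
#'
#' Per-patient change-score lines against months, one panel per metric,
#' with the zero (baseline) line marked. Points above zero are improvements
#' for increase-oriented metrics and below zero for decrease-oriented ones.
#'
#' @param scores Output of [change_from_baseline()].
#' @return A ggplot object.
#' @export
plot_change_scores <- function(scores) {
  ggplot2::ggplot(scores,
                  ggplot2::aes(x = .data$months, y = .data$value,
                               group = .data$patient_id,
                               colour = factor(.data$patient_id))) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "months", y = "change from baseline (proportion)",
                  colour = "patient")
}
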