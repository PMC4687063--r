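#' Plot a gaze trace with detected saccades
#'
#' Eye and target position against time, with detected (or ground-truth)
#' saccade onsets marked.
#'
#' @param trace A `gaze_trace`.
#' @param events Optional event table with `onset_ms` (from
#'   [detect_saccades()] or a simulation's ground truth).
#' @param window_ms Optional `c(from, to)` time window to display, ms.
#' @return A ggplot object.
#' @export
plot_gaze_trace <- function(trace, events = NULL, window_ms = NULL) {
  d <- as_tibble(trace)
  if (!is.null(window_ms)) {
    d <- d[d$time_ms >= window_ms[1] & d$time_ms <= window_ms[2], ]
    if (!is.null(events)) {
      events <- events[events$onset_ms >= window_ms[1] &
                         events$onset_ms <= window_ms[2], ]
    }
  }
  long <- tidyr::pivot_longer(d[c("time_ms", "eye_deg", "target_deg")],
                              cols = c("eye_deg", "target_deg"),
                              names_to = "channel", values_to = "deg")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time_ms, y = .data$deg,
                                          colour = .data$channel)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(x = "time (ms)", y = "position (deg)", colour = NULL)
  if (!is.null(events) && nrow(events) > 0) {
    p <- p + ggplot2::geom_vline(xintercept = events$onset_ms,
                                 linetype = 3, colour = "grey50")
  }
  p
}
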