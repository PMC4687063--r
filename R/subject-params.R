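#' Oculomotor parameters of a simulated subject
#'
#' Bundles the ground-truth parameters that drive every simulated recording:
#' the main-sequence constants, the gain and latency distributions for
#' visually guided saccades, the antisaccade direction-error probability, the
#' self-paced inter-saccadic-interval (ISI) distribution and the measurement
#' noise of the tracker.
#'
#' Defaults describe a mildly impaired adult performer recorded on an
#' infrared limbus tracker: peak velocities saturating at 500 deg/s with a
#' main-sequence constant of 8 deg, hypometric gain around 0.85, latencies
#' near 250 ms, a high (0.7) antisaccade error probability and self-paced
#' refixations every 0.8 s. Measurement noise defaults to the 0.1 deg
#' sensitivity typical of such trackers.
#'
#' @param vmax Asymptotic peak saccadic velocity, deg/s (> 0).
#' @param k Main-sequence constant of `V = vmax * (1 - exp(-A / k))`, deg
#'   (> 0).
#' @param gain_mean,gain_sd Mean and SD of the per-trial saccadic gain
#'   (amplitude / target step); `gain_mean` must be positive.
#' @param latency_mean_ms,latency_sd_ms Mean and SD of the saccadic latency
#'   distribution (log-normal, truncated below at 80 ms).
#' @param antisaccade_error_prob Probability, in \[0, 1\], that the primary
#'   antisaccade response goes toward the target (a direction error).
#' @param selfpaced_isi_mean_s Mean inter-saccadic interval on the self-paced
#'   task, seconds (> 0).
#' @param selfpaced_isi_shape Shape of the gamma ISI distribution (> 0);
#'   larger values give more regular pacing.
#' @param noise_sd_deg RMS amplitude of the additive white measurement noise,
#'   deg.
#'
#' @return An object of class `subject_params` (a named list).
#' @export
#' @examples
#' subject_params(vmax = 450, gain_mean = 0.8)
subject_params <- function(vmax = 500,
                           k = 8,
                           gain_mean = 0.85,
                           gain_sd = 0.08,
                           latency_mean_ms = 250,
                           latency_sd_ms = 50,
                           antisaccade_error_prob = 0.7,
                           selfpaced_isi_mean_s = 0.8,
                           selfpaced_isi_shape = 8,
                           noise_sd_deg = 0.1) {
  p <- list(
    vmax = vmax, k = k,
    gain_mean = gain_mean, gain_sd = gain_sd,
    latency_mean_ms = latency_mean_ms, latency_sd_ms = latency_sd_ms,
    antisaccade_error_prob = antisaccade_error_prob,
    selfpaced_isi_mean_s = selfpaced_isi_mean_s,
    selfpaced_isi_shape = selfpaced_isi_shape,
    noise_sd_deg = noise_sd_deg
  )
  validate_subject_params(p)
  structure(p, class = "subject_params")
}

validate_subject_params <- function(p) {
  stopifnot_msg(is.numeric(p$vmax), p$vmax > 0, msg = "`vmax` must be > 0")
  stopifnot_msg(is.numeric(p$k), p$k > 0, msg = "`k` must be > 0")
  stopifnot_msg(p$gain_mean > 0, msg = "`gain_mean` must be > 0")
  stopifnot_msg(p$gain_sd >= 0, msg = "`gain_sd` must be >= 0")
  stopifnot_msg(p$latency_mean_ms > 0, p$latency_sd_ms >= 0,
                msg = "latency parameters must be positive")
  stopifnot_msg(p$antisaccade_error_prob >= 0, p$antisaccade_error_prob <= 1,
                msg = "`antisaccade_error_prob` must lie in [0, 1]")
  stopifnot_msg(p$selfpaced_isi_mean_s > 0,
                msg = "`selfpaced_isi_mean_s` must be > 0")
  stopifnot_msg(p$selfpaced_isi_shape > 0,
                msg = "`selfpaced_isi_shape` must be > 0")
  stopifnot_msg(p$noise_sd_deg >= 0, msg = "`noise_sd_deg` must be >= 0")
  invisible(p)
}

stopifnot_msg <- function(..., msg) {
  ok <- vapply(list(...), function(x) isTRUE(all(x)), logical(1))
  if (!all(ok)) abort(msg, class = "sacclong_invalid_argument")
  invisible(TRUE)
}

#' Task protocol for a recording session
#'
#' Describes one saccadic task as presented to a subject. Three tasks are
#' supported:
#' \describe{
#'   \item{prosaccade}{60 pseudo-random horizontal target jumps with step
#'     magnitudes between 5 and 30 deg; the subject follows the target.}
#'   \item{antisaccade}{39 target presentations at 5 or 10 deg left or right
#'     of fixation; the subject must look to the mirror location. The target
#'     returns to fixation between trials.}
#'   \item{selfpaced}{two continuously lit targets at +/-10 deg; the subject
#'     refixates back and forth as fast as possible for 30 s.}
#' }
#'
#' @param task One of `"prosaccade"`, `"antisaccade"`, `"selfpaced"`.
#' @param n_trials Number of target steps (prosaccade/antisaccade). Defaults
#'   to 60 for prosaccades and 39 for antisaccades.
#' @param amplitude_range Prosaccade step magnitude range in deg, default
#'   `c(5, 30)`.
#' @param eccentricities Antisaccade target eccentricities in deg, default
#'   `c(5, 10)` (presented left and right).
#' @param target_offset_deg Self-paced target eccentricity, deg (targets at
#'   plus and minus this value), default 10.
#' @param duration_s Self-paced task duration in seconds, default 30.
#' @param sampling_rate_hz Sampling rate of the simulated recording, default
#'   1000 Hz.
#' @param fixation_interval_ms Range of the inter-trial fixation interval,
#'   ms; uniform between the two values.
#' @param hold_ms Antisaccade target on-time before it returns to fixation,
#'   ms.
#'
#' @return An object of class `task_protocol`.
#' @export
#' @examples
#' task_protocol("prosaccade")
#' task_protocol("selfpaced", duration_s = 10)
task_protocol <- function(task = c("prosaccade", "antisaccade", "selfpaced"),
                          n_trials = NULL,
                          amplitude_range = c(5, 30),
                          eccentricities = c(5, 10),
                          target_offset_deg = 10,
                          duration_s = 30,
                          sampling_rate_hz = 1000,
                          fixation_interval_ms = c(1200, 1800),
                          hold_ms = 1000) {
  task <- match.arg(task)
  if (is.null(n_trials)) {
    n_trials <- switch(task, prosaccade = 60, antisaccade = 39, selfpaced = NA_integer_)
  }
  stopifnot_msg(sampling_rate_hz >= 250,
                msg = "`sampling_rate_hz` must be at least 250 Hz")
  if (task != "selfpaced") {
    stopifnot_msg(is.numeric(n_trials), n_trials >= 1,
                  msg = "`n_trials` must be a positive count")
  }
  stopifnot_msg(length(amplitude_range) == 2, amplitude_range[1] > 0,
                amplitude_range[2] >= amplitude_range[1],
                msg = "`amplitude_range` must be increasing and positive")
  stopifnot_msg(all(eccentricities > 0),
                msg = "`eccentricities` must be positive")
  stopifnot_msg(duration_s > 0, msg = "`duration_s` must be > 0")
  structure(
    list(
      task = task,
      n_trials = as.integer(n_trials),
      amplitude_range = amplitude_range,
      eccentricities = eccentricities,
      target_offset_deg = target_offset_deg,
      duration_s = duration_s,
      sampling_rate_hz = sampling_rate_hz,
      fixation_interval_ms = fixation_interval_ms,
      hold_ms = hold_ms
    ),
    class = "task_protocol"
  )
}

# mean/sd (natural scale) -> meanlog/sdlog of a log-normal
lnorm_pars <- function(mean, sd) {
  sdlog <- sqrt(log(1 + (sd / mean)^2))
  list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

# latency draws: log-normal truncated to [80, 700] ms by resampling
draw_latencies <- function(n, mean_ms, sd_ms, lower = 80, upper = 700) {
  lp <- lnorm_pars(mean_ms, max(sd_ms, 1e-9))
  out <- rlnorm(n, lp$meanlog, lp$sdlog)
  bad <- which(out < lower | out > upper)
  tries <- 0L
  while (length(bad) > 0 && tries < 1000L) {
    out[bad] <- rlnorm(length(bad), lp$meanlog, lp$sdlog)
    bad <- which(out < lower | out > upper)
    tries <- tries + 1L
  }
  out[out < lower] <- lower
  out[out > upper] <- upper
  out
}

# gain draws, kept away from zero so every response is a real saccade
draw_gains <- function(n, mean, sd) {
  g <- rnorm(n, mean, sd)
  pmax(g, 0.3)
}
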