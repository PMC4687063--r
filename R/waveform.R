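#' Main-sequence peak velocity
#'
#' Evaluates the saturating-exponential main sequence
#' `V = vmax * (1 - exp(-|A| / k))` linking saccade amplitude to peak
#' velocity.
#'
#' @param amplitude_deg Saccade amplitude(s), deg (sign ignored).
#' @param vmax Asymptotic peak velocity, deg/s.
#' @param k Main-sequence constant, deg.
#' @return Peak velocity, deg/s.
#' @export
#' @examples
#' main_sequence_velocity(10, vmax = 500, k = 8) # ~356.7 deg/s
main_sequence_velocity <- function(amplitude_deg, vmax, k) {
  vmax * (1 - exp(-abs(amplitude_deg) / k))
}

#' Simulate one saccade waveform
#'
#' Generates the noise-free position profile of a single horizontal saccade
#' under a symmetric raised-cosine velocity profile. The peak velocity is
#' taken from the subject's main sequence, and with the raised-cosine
#' convention the duration is exactly `2 * |amplitude| / peak_velocity`
#' (mean velocity is half the peak). The returned ground truth is exact,
#' i.e. pre-noise.
#'
#' @param amplitude_deg Signed saccade amplitude, deg; must be non-zero.
#' @param subject A [subject_params()] object supplying `vmax` and `k`.
#' @param sampling_rate_hz Sampling rate, Hz; must be at least 250 so the
#'   waveform is resolved.
#'
#' @return A list with `position_deg` (displacement samples running from 0 to
#'   `amplitude_deg`, one per sample period starting at the onset sample),
#'   `duration_ms`, `peak_velocity_dps` and `n_samples`.
#' @export
#' @examples
#' w <- simulate_saccade_waveform(10, subject_params(vmax = 500, k = 8))
#' w$peak_velocity_dps # 500 * (1 - exp(-10/8))
simulate_saccade_waveform <- function(amplitude_deg, subject,
                                      sampling_rate_hz = 1000) {
  stopifnot_msg(is.numeric(amplitude_deg), length(amplitude_deg) == 1,
                amplitude_deg != 0,
                msg = "`amplitude_deg` must be a single non-zero number")
  stopifnot_msg(sampling_rate_hz >= 250,
                msg = "`sampling_rate_hz` below 250 Hz cannot resolve a saccade waveform")
  a <- abs(amplitude_deg)
  vp <- main_sequence_velocity(a, subject$vmax, subject$k)
  duration_s <- 2 * a / vp
  n <- max(2L, round(duration_s * sampling_rate_hz))
  x <- seq_len(n) / n                     # fraction of the movement elapsed
  pos <- amplitude_deg * (x - sin(2 * pi * x) / (2 * pi))
  list(
    position_deg = pos,
    duration_ms = duration_s * 1000,
    peak_velocity_dps = vp,
    n_samples = n
  )
}
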