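#' Simulate one recording session
#'
#' Generates a complete 1 kHz (by default) gaze-position recording for one
#' task, together with the exact ground truth of every simulated saccade and
#' trial. The same `seed` with the same protocol and subject reproduces the
#' session exactly.
#'
#' Task-specific behaviour:
#' * **prosaccade** — the target makes `n_trials` pseudo-random horizontal
#'   jumps with magnitudes uniform over `amplitude_range`; direction runs are
#'   limited to four consecutive same-direction steps and the target is kept
#'   within +/-30 deg. The eye follows each step after a log-normal latency
#'   with a normally distributed gain.
#' * **antisaccade** — the target steps from fixation to an eccentric
#'   location and back; the primary response goes toward the target with
#'   probability `antisaccade_error_prob` (an error) and to the mirror
#'   location otherwise. A non-scored return saccade brings the eye back to
#'   fixation after the target does.
#' * **selfpaced** — the eye alternates between the two lit targets with
#'   gamma-distributed inter-saccadic intervals until `duration_s` elapses;
#'   the target channel is constant because no target ever steps.
#'
#' White Gaussian measurement noise of SD `subject$noise_sd_deg` is added to
#' the eye channel when `trace = TRUE`.
#'
#' @param protocol A [task_protocol()].
#' @param subject A [subject_params()].
#' @param seed Integer seed; required, so that every session is reproducible.
#' @param trace If `FALSE`, skip waveform assembly and return only the
#'   ground-truth event and trial tables (fast path for Monte-Carlo work on
#'   the generator itself).
#'
#' @return An object of class `saccade_session`: a list with elements
#'   `trace` (a `gaze_trace` tibble with columns `time_ms`, `eye_deg`,
#'   `target_deg`, or `NULL` when `trace = FALSE`), `events` (ground-truth
#'   saccades: `onset_ms`, `offset_ms`, `amplitude_deg`,
#'   `peak_velocity_dps`), `trials` (task-dependent ground-truth trial
#'   table), `protocol`, `subject` and `seed`.
#' @export
#' @examples
#' s <- simulate_session(task_protocol("selfpaced", duration_s = 5),
#'                       subject_params(), seed = 1)
#' nrow(s$events)
simulate_session <- function(protocol, subject, seed, trace = TRUE) {
  stopifnot_msg(inherits(protocol, "task_protocol"),
                msg = "`protocol` must be a task_protocol()")
  stopifnot_msg(inherits(subject, "subject_params"),
                msg = "`subject` must be a subject_params()")
  stopifnot_msg(is.numeric(seed), length(seed) == 1,
                msg = "`seed` is required for reproducibility")
  set.seed(as.integer(seed))

  plan <- switch(protocol$task,
    prosaccade  = plan_prosaccade(protocol, subject),
    antisaccade = plan_antisaccade(protocol, subject),
    selfpaced   = plan_selfpaced(protocol, subject)
  )

  events <- build_events(plan, subject, protocol$sampling_rate_hz)
  gt <- events[order(events$onset_ms), ]

  trace_tbl <- NULL
  if (isTRUE(trace)) {
    trace_tbl <- assemble_trace(plan, gt, subject, protocol)
  }

  structure(
    list(trace = trace_tbl, events = gt, trials = plan$trials,
         protocol = protocol, subject = subject, seed = as.integer(seed)),
    class = "saccade_session"
  )
}

# ---- task planners -------------------------------------------------------
# A plan is: saccades (onset_ms, amplitude_deg, start_eye_deg),
# target_steps (time_ms, target_deg after the step), trials, end_ms,
# eye0_deg, target0_deg.

plan_prosaccade <- function(protocol, subject) {
  n <- protocol$n_trials
  lo <- protocol$amplitude_range[1]
  hi <- protocol$amplitude_range[2]
  bound <- 30

  intervals <- runif(n, protocol$fixation_interval_ms[1],
                     protocol$fixation_interval_ms[2])
  step_times <- 1000 + cumsum(intervals)

  # pseudo-random directions: at most 4 consecutive same-direction steps,
  # target kept within +/- bound
  sgn <- integer(n); amp <- numeric(n); pos <- numeric(n + 1); pos[1] <- 0
  run_dir <- 0L; run_len <- 0L
  for (i in seq_len(n)) {
    p <- pos[i]
    feasible <- c(-1, 1)[c(p - lo >= -bound, p + lo <= bound)]
    s <- if (run_len >= 4L && length(feasible) > 1L) {
      -run_dir
    } else if (length(feasible) == 1L) {
      feasible
    } else {
      sample(c(-1, 1), 1)
    }
    a_hi <- min(hi, if (s > 0) bound - p else p + bound)
    amp[i] <- runif(1, lo, a_hi)
    sgn[i] <- s
    pos[i + 1] <- p + s * amp[i]
    if (s == run_dir) run_len <- run_len + 1L else { run_dir <- s; run_len <- 1L }
  }
  step_amp <- sgn * amp

  latency <- draw_latencies(n, subject$latency_mean_ms, subject$latency_sd_ms)
  gain <- draw_gains(n, subject$gain_mean, subject$gain_sd)
  exec_amp <- gain * step_amp
  onset <- step_times + latency
  eye_start <- c(0, cumsum(exec_amp))[seq_len(n)]

  trials <- tibble(
    trial = seq_len(n),
    step_time_ms = step_times,
    step_amplitude_deg = step_amp,
    latency_ms = latency,
    gain = gain,
    response_amplitude_deg = exec_amp
  )
  list(
    saccades = tibble(onset_ms = onset, amplitude_deg = exec_amp,
                      start_eye_deg = eye_start),
    target_steps = tibble(time_ms = step_times, target_deg = pos[-1]),
    trials = trials,
    end_ms = max(onset) + 1000,
    eye0_deg = 0, target0_deg = 0
  )
}

plan_antisaccade <- function(protocol, subject) {
  n <- protocol$n_trials
  ecc_set <- c(-protocol$eccentricities, protocol$eccentricities)
  ecc <- sample(ecc_set, n, replace = TRUE)

  l1 <- draw_latencies(n, subject$latency_mean_ms, subject$latency_sd_ms)
  l2 <- draw_latencies(n, subject$latency_mean_ms, subject$latency_sd_ms)
  gain <- draw_gains(n, subject$gain_mean, subject$gain_sd)
  is_error <- rbinom(n, 1, subject$antisaccade_error_prob) == 1
  dir <- ifelse(is_error, sign(ecc), -sign(ecc))
  resp_amp <- dir * gain * abs(ecc)

  hold <- protocol$hold_ms
  cycle <- hold + runif(n, protocol$fixation_interval_ms[1],
                        protocol$fixation_interval_ms[2])
  step_times <- 1000 + c(0, cumsum(cycle[-n]))
  return_times <- step_times + hold

  onset1 <- step_times + l1
  onset2 <- return_times + l2

  saccades <- tibble(
    onset_ms = c(onset1, onset2),
    amplitude_deg = c(resp_amp, -resp_amp),
    start_eye_deg = c(rep(0, n), resp_amp)
  )
  target_steps <- tibble(
    time_ms = c(step_times, return_times),
    target_deg = c(ecc, rep(0, n))
  )
  ord <- order(target_steps$time_ms)
  trials <- tibble(
    trial = seq_len(n),
    step_time_ms = step_times,
    step_amplitude_deg = ecc,
    latency_ms = l1,
    response_amplitude_deg = resp_amp,
    is_error = is_error
  )
  list(
    saccades = saccades,
    target_steps = target_steps[ord, ],
    trials = trials,
    end_ms = max(onset2) + 1000,
    eye0_deg = 0, target0_deg = 0
  )
}

plan_selfpaced <- function(protocol, subject) {
  off <- protocol$target_offset_deg
  dur_ms <- protocol$duration_s * 1000
  shape <- subject$selfpaced_isi_shape
  scale <- subject$selfpaced_isi_mean_s / shape

  dir1 <- sample(c(-1, 1), 1)
  g0 <- draw_gains(1, subject$gain_mean, subject$gain_sd)
  eye0 <- -dir1 * g0 * off          # start fixating one of the two targets

  onsets <- numeric(0); t <- 300    # first refixation shortly after start
  repeat {
    onsets <- c(onsets, t)
    isi <- max(rgamma(1, shape = shape, scale = scale), 0.15)
    t <- t + isi * 1000
    if (t > dur_ms + 500) break
  }
  m <- length(onsets)
  gains <- draw_gains(m, subject$gain_mean, subject$gain_sd)
  goal <- dir1 * off * (-1)^(seq_len(m) - 1)   # alternating targets
  amp <- numeric(m); eye <- numeric(m + 1); eye[1] <- eye0
  for (i in seq_len(m)) {
    amp[i] <- gains[i] * (goal[i] - eye[i])
    eye[i + 1] <- eye[i] + amp[i]
  }
  trials <- tibble(
    refixation = seq_len(m),
    onset_ms = onsets,
    amplitude_deg = amp,
    isi_s = c(NA_real_, diff(onsets)) / 1000
  )
  list(
    saccades = tibble(onset_ms = onsets, amplitude_deg = amp,
                      start_eye_deg = eye[seq_len(m)]),
    target_steps = tibble(time_ms = numeric(0), target_deg = numeric(0)),
    trials = trials,
    end_ms = dur_ms + 1500,
    eye0_deg = eye0, target0_deg = 0
  )
}

# ---- assembly ------------------------------------------------------------

build_events <- function(plan, subject, fs) {
  sac <- plan$saccades
  if (nrow(sac) == 0) {
    return(tibble(onset_ms = numeric(0), offset_ms = numeric(0),
                  amplitude_deg = numeric(0), peak_velocity_dps = numeric(0)))
  }
  vp <- main_sequence_velocity(sac$amplitude_deg, subject$vmax, subject$k)
  dur_ms <- 2 * abs(sac$amplitude_deg) / vp * 1000
  tibble(
    onset_ms = sac$onset_ms,
    offset_ms = sac$onset_ms + dur_ms,
    amplitude_deg = sac$amplitude_deg,
    peak_velocity_dps = vp
  )
}

assemble_trace <- function(plan, events, subject, protocol) {
  fs <- protocol$sampling_rate_hz
  dt_ms <- 1000 / fs
  n_samp <- ceiling(plan$end_ms / dt_ms) + 1L
  time_ms <- (seq_len(n_samp) - 1L) * dt_ms

  # target channel: step function
  target <- rep(plan$target0_deg, n_samp)
  ts <- plan$target_steps
  if (nrow(ts) > 0) {
    for (i in seq_len(nrow(ts))) {
      j <- floor(ts$time_ms[i] / dt_ms) + 1L
      if (j <= n_samp) target[j:n_samp] <- ts$target_deg[i]
    }
  }

  # eye channel: fixations joined by raised-cosine saccade segments
  sac <- plan$saccades[order(plan$saccades$onset_ms), ]
  eye <- rep(plan$eye0_deg, n_samp)
  for (i in seq_len(nrow(sac))) {
    w <- simulate_saccade_waveform(sac$amplitude_deg[i], subject, fs)
    j0 <- floor(sac$onset_ms[i] / dt_ms) + 1L
    idx <- j0 + seq_len(w$n_samples)
    idx <- idx[idx <= n_samp]
    start <- sac$start_eye_deg[i]
    eye[idx] <- start + w$position_deg[seq_along(idx)]
    land <- max(idx)
    if (land < n_samp) eye[(land + 1L):n_samp] <- start + sac$amplitude_deg[i]
  }
  if (subject$noise_sd_deg > 0) {
    eye <- eye + rnorm(n_samp, 0, subject$noise_sd_deg)
  }
  new_gaze_trace(
    tibble(time_ms = time_ms, eye_deg = eye, target_deg = target),
    sampling_rate_hz = fs, task = protocol$task
  )
}

#' @export
print.saccade_session <- function(x, ...) {
  cat("<saccade_session>", x$protocol$task,
      "| events:", nrow(x$events),
      "| trials:", nrow(x$trials),
      "| seed:", x$seed, "\n")
  invisible(x)
}
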