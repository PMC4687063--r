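#' Construct a gaze trace
#'
#' A gaze trace is a tibble with columns `time_ms` (strictly increasing,
#' uniformly sampled), `eye_deg` and `target_deg`, carrying the sampling
#' rate and task label as attributes. Rightward is positive; time is ms
#' from session start.
#'
#' @param data Data frame with `time_ms`, `eye_deg`, `target_deg`.
#' @param sampling_rate_hz Sampling rate, Hz; inferred from the time column
#'   when omitted.
#' @param task Task label (`"prosaccade"`, `"antisaccade"`, `"selfpaced"`)
#'   or `NULL`.
#' @return A `gaze_trace` tibble.
#' @export
as_gaze_trace <- function(data, sampling_rate_hz = NULL, task = NULL) {
  problems <- validate_trace_frame(data, sampling_rate_hz)
  if (length(problems) > 0) {
    abort(c("not a valid gaze trace:", problems),
          class = "sacclong_validation_error")
  }
  fs <- sampling_rate_hz %||% infer_sampling_rate(data$time_ms)
  new_gaze_trace(as_tibble(data), sampling_rate_hz = fs, task = task)
}

new_gaze_trace <- function(data, sampling_rate_hz, task = NULL) {
  structure(data,
            class = c("gaze_trace", class(tibble())),
            sampling_rate_hz = sampling_rate_hz,
            task = task)
}

infer_sampling_rate <- function(time_ms) {
  1000 / median(diff(time_ms))
}

trace_sampling_rate <- function(trace) {
  attr(trace, "sampling_rate_hz") %||% infer_sampling_rate(trace$time_ms)
}

check_trace_frame <- function(trace) {
  stopifnot_msg(is.data.frame(trace),
                all(c("time_ms", "eye_deg") %in% names(trace)),
                msg = "`trace` must be a data frame with `time_ms` and `eye_deg` columns")
  invisible(trace)
}

validate_trace_frame <- function(data, declared_rate = NULL) {
  problems <- character(0)
  required <- c("time_ms", "eye_deg", "target_deg")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    return(paste("missing column(s):", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(data) < 3) problems <- c(problems, "fewer than 3 samples")
  for (col in required) {
    if (!is.numeric(data[[col]])) {
      problems <- c(problems, paste0("column `", col, "` is not numeric"))
    }
  }
  if (length(problems) > 0) return(problems)
  dt <- diff(data$time_ms)
  bad <- which(dt <= 0)
  if (length(bad) > 0) {
    problems <- c(problems,
                  paste0("time is not strictly increasing (first offending row: ",
                         bad[1] + 1L, ")"))
  } else {
    rel_spread <- (max(dt) - min(dt)) / median(dt)
    if (rel_spread > 0.01) {
      problems <- c(problems,
                    paste0("sampling is not uniform within 1% (rows ",
                           which.max(dt) + 1L, " / ", which.min(dt) + 1L, ")"))
    }
    if (!is.null(declared_rate)) {
      inferred <- 1000 / median(dt)
      if (abs(inferred - declared_rate) / declared_rate > 0.01) {
        problems <- c(problems,
                      sprintf("declared sampling rate %g Hz inconsistent with time spacing (inferred %g Hz)",
                              declared_rate, inferred))
      }
    }
  }
  problems
}

#' Validate a trace file on disk
#'
#' Schema-checks a session CSV (columns `time_ms`, `eye_deg`, `target_deg`;
#' strictly increasing, uniformly spaced time; sampling rate consistent with
#' any declared rate) and reports every violation found.
#'
#' @param path Path to a trace CSV.
#' @param sampling_rate_hz Optional declared sampling rate to check the time
#'   column against (within 1 percent).
#' @param task Optional task label attached to the returned trace.
#' @return A list with `ok` (logical), `trace` (the parsed `gaze_trace`, or
#'   `NULL`) and `problems` (character vector of violations, with row
#'   references where applicable).
#' @export
validate_trace_file <- function(path, sampling_rate_hz = NULL, task = NULL) {
  if (!file.exists(path)) {
    return(list(ok = FALSE, trace = NULL,
                problems = paste("file not found:", path)))
  }
  data <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) NULL
  )
  if (is.null(data)) {
    return(list(ok = FALSE, trace = NULL, problems = "file could not be parsed as CSV"))
  }
  problems <- validate_trace_frame(data, sampling_rate_hz)
  if (length(problems) > 0) {
    return(list(ok = FALSE, trace = NULL, problems = problems))
  }
  fs <- sampling_rate_hz %||% infer_sampling_rate(data$time_ms)
  list(ok = TRUE,
       trace = new_gaze_trace(as_tibble(data), sampling_rate_hz = fs,
                              task = task),
       problems = character(0))
}

#' Read a gaze trace CSV
#'
#' Reads and validates a session trace file, aborting with the full list of
#' violations if the file is malformed.
#'
#' @inheritParams validate_trace_file
#' @return A `gaze_trace` tibble.
#' @export
read_gaze_trace <- function(path, sampling_rate_hz = NULL, task = NULL) {
  v <- validate_trace_file(path, sampling_rate_hz, task)
  if (!v$ok) {
    abort(c(paste0("invalid trace file `", path, "`:"), v$problems),
          class = "sacclong_validation_error")
  }
  v$trace
}

#' Write a gaze trace CSV
#'
#' @param trace A `gaze_trace`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gaze_trace <- function(trace, path) {
  readr::write_csv(as_tibble(trace)[c("time_ms", "eye_deg", "target_deg")],
                   path, progress = FALSE)
  invisible(path)
}

#' Write a simulated session to disk
#'
#' Writes the trace CSV plus a ground-truth sidecar CSV listing every
#' simulated saccade (`onset_ms`, `offset_ms`, `amplitude_deg`,
#' `peak_velocity_dps`).
#'
#' @param session A [simulate_session()] result (simulated with
#'   `trace = TRUE`).
#' @param dir Output directory (created if needed).
#' @param stem File stem; files are `<stem>.csv` and
#'   `<stem>_ground_truth.csv`.
#' @return Named character vector of the two paths, invisibly.
#' @export
write_session <- function(session, dir, stem) {
  stopifnot_msg(inherits(session, "saccade_session"), !is.null(session$trace),
                msg = "`session` must be a saccade_session simulated with trace = TRUE")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  trace_path <- file.path(dir, paste0(stem, ".csv"))
  gt_path <- file.path(dir, paste0(stem, "_ground_truth.csv"))
  write_gaze_trace(session$trace, trace_path)
  readr::write_csv(session$events, gt_path, progress = FALSE)
  invisible(c(trace = trace_path, ground_truth = gt_path))
}
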