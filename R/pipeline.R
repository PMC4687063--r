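#' Pipeline configuration
#'
#' Bundles everything one end-to-end run needs: where to write outputs, the
#' cohort to simulate (or the manifest/trace directory to read), detection
#' thresholds, metric settings and the random seed. A configuration can
#' also be read from a YAML file with [read_pipeline_config()].
#'
#' @param out_dir Output directory; created if needed.
#' @param seed Integer seed governing every random draw of the run.
#' @param cohort A [cohort_config()]; its own seed is overridden by `seed`.
#' @param tasks Tasks recorded at each visit.
#' @param protocols Optional named list of [task_protocol()] overrides.
#' @param thresholds A [saccade_thresholds()].
#' @param min_fit_n Minimum saccade count for main-sequence / HSEM-alpha
#'   fits.
#' @param selfpaced_window_s Self-paced scoring window, seconds.
#' @param simulate If `TRUE` the cohort is simulated; if `FALSE`,
#'   `manifest_path` and `trace_dir` must point at existing recordings laid
#'   out as the simulate stage writes them.
#' @param manifest_path,trace_dir Inputs for `simulate = FALSE`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            seed = 1,
                            cohort = cohort_config(seed = seed),
                            tasks = c("prosaccade", "antisaccade", "selfpaced"),
                            protocols = NULL,
                            thresholds = saccade_thresholds(),
                            min_fit_n = 10,
                            selfpaced_window_s = 30,
                            simulate = TRUE,
                            manifest_path = NULL,
                            trace_dir = NULL) {
  cohort$seed <- as.integer(seed)
  structure(
    list(out_dir = out_dir, seed = as.integer(seed), cohort = cohort,
         tasks = tasks, protocols = protocols, thresholds = thresholds,
         min_fit_n = min_fit_n, selfpaced_window_s = selfpaced_window_s,
         simulate = simulate, manifest_path = manifest_path,
         trace_dir = trace_dir),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' The file may contain sections `cohort`, `protocols`, `thresholds` and
#' top-level keys `out_dir`, `seed`, `tasks`, `min_fit_n`,
#' `selfpaced_window_s`, `simulate`, `manifest_path`, `trace_dir`; absent
#' keys fall back to the [pipeline_config()] defaults.
#'
#' @param path Path to a YAML file.
#' @param out_dir Optional override of the configured output directory.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, out_dir = NULL) {
  stopifnot_msg(file.exists(path),
                msg = paste("config file not found:", path))
  y <- yaml::read_yaml(path)
  coh <- do.call(cohort_config, y$cohort %||% list())
  thr <- do.call(saccade_thresholds, y$thresholds %||% list())
  protos <- NULL
  if (!is.null(y$protocols)) {
    protos <- lapply(names(y$protocols), function(nm) {
      do.call(task_protocol, c(list(task = nm), y$protocols[[nm]]))
    })
    names(protos) <- names(y$protocols)
  }
  pipeline_config(
    out_dir = out_dir %||% y$out_dir %||% ".",
    seed = y$seed %||% 1,
    cohort = coh,
    tasks = y$tasks %||% c("prosaccade", "antisaccade", "selfpaced"),
    protocols = protos,
    thresholds = thr,
    min_fit_n = y$min_fit_n %||% 10,
    selfpaced_window_s = y$selfpaced_window_s %||% 30,
    simulate = y$simulate %||% TRUE,
    manifest_path = y$manifest_path,
    trace_dir = y$trace_dir
  )
}

#' A small demonstration configuration
#'
#' Three patients (two treated), short follow-up, reduced trial counts and a
#' 10-s self-paced task: runs end-to-end in seconds while exercising every
#' stage.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed.
#' @return A `pipeline_config`.
#' @export
demo_pipeline_config <- function(out_dir, seed = 1) {
  pipeline_config(
    out_dir = out_dir, seed = seed,
    cohort = cohort_config(n_patients = 3, n_treated = 2,
                           followup_months_range = c(20, 28),
                           n_pretreatment_patients = 1,
                           n_pretreatment_visits = 1,
                           seed = seed),
    protocols = list(
      prosaccade = task_protocol("prosaccade", n_trials = 20),
      antisaccade = task_protocol("antisaccade", n_trials = 15),
      selfpaced = task_protocol("selfpaced", duration_s = 10)
    ),
    selfpaced_window_s = 10
  )
}

#' Run the full analysis pipeline
#'
#' Executes simulate (optional) -> detect -> metrics -> longitudinal,
#' writing every stage's artifacts under `config$out_dir` and a run
#' manifest (`run_manifest.json`) recording the configuration hash, seed,
#' per-stage counts and MD5 checksums of all outputs. A rerun with the same
#' configuration and seed reproduces the metric CSVs bit for bit. Any stage
#' failure halts the run naming the stage; earlier outputs are preserved.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage log messages.
#' @return Invisibly, a list with the output paths, the per-stage counts
#'   and the parsed results (`session_metrics`, `trials_long`,
#'   `change_scores`, `lme_results`).
#' @export
#' @examples
#' \donttest{
#' res <- run_pipeline(demo_pipeline_config(tempfile("demo"), seed = 1))
#' res$lme_results
#' }
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot_msg(inherits(config, "pipeline_config"),
                msg = "`config` must be a pipeline_config()")
  log <- function(...) if (!quiet) message("[sacclong] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage `", name, "` failed: ",
                   conditionMessage(e)),
            class = "sacclong_stage_error")
    })
  }
  counts <- list()
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  # ---- stage: input validation / simulate --------------------------------
  if (!config$simulate) {
    stage("validate", {
      stopifnot_msg(!is.null(config$manifest_path),
                    file.exists(config$manifest_path %||% ""),
                    msg = "`manifest_path` must exist when simulate = FALSE")
      stopifnot_msg(!is.null(config$trace_dir),
                    dir.exists(config$trace_dir %||% ""),
                    msg = "`trace_dir` must exist when simulate = FALSE")
    })
    manifest <- readr::read_csv(config$manifest_path, show_col_types = FALSE)
    trace_dir <- config$trace_dir
    sessions <- NULL
  } else {
    cohort <- stage("simulate",
                    simulate_cohort(config$cohort, level = "traces",
                                    tasks = config$tasks,
                                    protocols = config$protocols))
    manifest <- cohort$manifest
    sessions <- cohort$sessions
    trace_dir <- file.path(out, "traces")
    dir.create(trace_dir, showWarnings = FALSE)
    stage("simulate", {
      readr::write_csv(manifest, file.path(out, "manifest.csv"),
                       progress = FALSE)
      for (key in names(sessions)) {
        write_session(sessions[[key]], trace_dir, key)
      }
    })
    counts$visits_simulated <- nrow(manifest)
    counts$sessions_simulated <- length(sessions)
    log("simulate: ", nrow(manifest), " visits, ", length(sessions),
        " sessions")
  }

  # ---- stage: detect -----------------------------------------------------
  ev_dir <- file.path(out, "events"); dir.create(ev_dir, showWarnings = FALSE)
  tr_dir <- file.path(out, "trials"); dir.create(tr_dir, showWarnings = FALSE)
  analysed <- stage("detect", {
    res <- list()
    for (i in seq_len(nrow(manifest))) {
      sid <- manifest$session_id[i]
      for (tk in config$tasks) {
        key <- paste0(sid, "_", tk)
        trace <- if (!is.null(sessions)) {
          sessions[[key]]$trace
        } else {
          read_gaze_trace(file.path(trace_dir, paste0(key, ".csv")),
                          task = tk)
        }
        if (is.null(trace)) next
        a <- analyse_trace(trace, config$thresholds, task = tk)
        readr::write_csv(a$events, file.path(ev_dir, paste0(key, ".csv")),
                         progress = FALSE)
        if (!is.null(a$trials)) {
          readr::write_csv(a$trials, file.path(tr_dir, paste0(key, ".csv")),
                           progress = FALSE)
        }
        res[[key]] <- a
      }
    }
    res
  })
  counts$sessions_read <- length(analysed)
  counts$events_detected <- sum(vapply(analysed,
                                       function(a) nrow(a$events), numeric(1)))
  excl <- unlist(lapply(analysed, function(a) a$trials$exclusion_reason))
  counts$trials_excluded <- as.list(table(excl[excl != "none"]))
  log("detect: ", counts$events_detected, " events in ",
      counts$sessions_read, " sessions")

  # ---- stage: metrics ----------------------------------------------------
  metrics_res <- stage("metrics", {
    rows <- list(); long <- list()
    for (i in seq_len(nrow(manifest))) {
      sid <- manifest$session_id[i]
      get <- function(tk) analysed[[paste0(sid, "_", tk)]]
      sm <- session_metrics(prosaccade = get("prosaccade"),
                            antisaccade = get("antisaccade"),
                            selfpaced = get("selfpaced"),
                            min_fit_n = config$min_fit_n,
                            selfpaced_window_s = config$selfpaced_window_s)
      meta <- manifest[i, c("patient_id", "session_id", "months", "group")]
      rows[[i]] <- dplyr::bind_cols(meta, sm[names(sm) != "isi_s"],
                                    tibble(isi_mean_s = mean(sm$isi_s[[1]])))
      long[[i]] <- session_trial_long(meta, get("prosaccade"), sm$isi_s[[1]])
    }
    list(metrics = bind_rows(rows), long = bind_rows(long))
  })
  session_metrics_tbl <- metrics_res$metrics
  trials_long <- metrics_res$long
  readr::write_csv(session_metrics_tbl,
                   file.path(out, "session_metrics.csv"), progress = FALSE)
  readr::write_csv(trials_long, file.path(out, "trials_long.csv"),
                   progress = FALSE)
  counts$visits_summarised <- nrow(session_metrics_tbl)
  log("metrics: ", nrow(session_metrics_tbl), " visit summaries, ",
      nrow(trials_long), " trial-level rows")

  # ---- stage: longitudinal ----------------------------------------------
  longit <- stage("longitudinal", {
    metrics_long <- session_metrics_tbl |>
      tidyr::pivot_longer(
        cols = dplyr::any_of(c("vmax_dps", "hsem_alpha", "gain",
                               "latency_ms", "antisaccade_error_pct",
                               "selfpaced_count", "isi_mean_s")),
        names_to = "metric", values_to = "value"
      ) |>
      mutate(metric = ifelse(.data$metric == "isi_mean_s", "isi_s",
                             .data$metric)) |>
      select("patient_id", "months", "metric", "value")
    scores <- change_from_baseline(metrics_long)
    lme_rows <- list()
    for (mm in intersect(c("isi_s", "gain", "latency_ms"),
                         unique(trials_long$metric))) {
      fit <- fit_saccade_lme(trials_long, metric = mm)
      lme_rows[[mm]] <- tidy(fit)
    }
    list(scores = scores, lme = bind_rows(lme_rows))
  })
  readr::write_csv(longit$scores, file.path(out, "change_scores.csv"),
                   progress = FALSE)
  readr::write_csv(longit$lme, file.path(out, "lme_results.csv"),
                   progress = FALSE)
  log("longitudinal: ", nrow(longit$scores), " change scores, ",
      nrow(longit$lme), " LME terms")

  # ---- run manifest ------------------------------------------------------
  csvs <- list.files(out, pattern = "\\.csv$", recursive = TRUE,
                     full.names = TRUE)
  sums <- tools::md5sum(csvs)
  run_manifest <- list(
    package_version = as.character(utils::packageVersion("sacclong")),
    seed = config$seed,
    config_hash = rlang::hash(config),
    timestamp = format(Sys.time(), tz = "UTC"),
    counts = counts,
    checksums = as.list(setNames(unname(sums),
                                 sub(paste0("^", out, "/?"), "", names(sums))))
  )
  jsonlite::write_json(run_manifest, file.path(out, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(
    out_dir = out,
    counts = counts,
    session_metrics = session_metrics_tbl,
    trials_long = trials_long,
    change_scores = longit$scores,
    lme_results = longit$lme
  ))
}

# trial-level long rows for the LME stage: per-trial gain and latency from
# the prosaccade session, per-pair ISI from the self-paced session
session_trial_long <- function(meta, pro, isi) {
  rows <- list()
  if (!is.null(pro) && !is.null(pro$trials)) {
    sc <- pro$trials[pro$trials$exclusion_reason == "none", ]
    if (nrow(sc) > 0) {
      rows$gain <- tibble(metric = "gain", value = sc$gain)
      rows$lat <- tibble(metric = "latency_ms", value = sc$latency_ms)
    }
  }
  if (length(isi) > 0) {
    rows$isi <- tibble(metric = "isi_s", value = isi)
  }
  if (length(rows) == 0) return(NULL)
  dplyr::bind_cols(meta[rep(1, sum(vapply(rows, nrow, numeric(1)))), ],
                   bind_rows(rows))
}
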