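#' Configuration of a simulated longitudinal cohort
#'
#' Describes a small clinical cohort followed over months to years: how many
#' patients, how many are treated, follow-up length, visit spacing, the
#' baseline oculomotor parameters, per-group linear drifts of the metric
#' means (per month), and between-patient variation as per-metric random
#' intercepts. The defaults emulate a nine-patient cohort with eight treated
#' patients, one never-treated patient, and two treated patients each
#' recorded twice before starting treatment; visits are 7-12 months apart
#' over 33-61 months of follow-up.
#'
#' Default drifts take the published per-month fixed-effect estimates for a
#' treated and an untreated group as generative truth: inter-saccadic
#' interval -0.001 (treated) vs +0.026 (untreated) s/month, gain +0.001 vs
#' -0.004 per month, latency -0.000301 s/month (treated) vs no drift
#' untreated.
#'
#' Recognised metric names for `treated_slopes`, `untreated_slopes` and
#' `random_intercept_sd`: `isi_s`, `gain`, `latency_ms`, `vmax_dps`,
#' `error_prob`.
#'
#' @param n_patients,n_treated Cohort size and number of treated patients
#'   (`n_treated <= n_patients`).
#' @param followup_months_range Range of per-patient follow-up length,
#'   months.
#' @param visit_interval_months_range Range of the interval between
#'   successive visits, months.
#' @param n_pretreatment_patients,n_pretreatment_visits How many treated
#'   patients also have recordings before treatment onset, and how many
#'   such visits each.
#' @param baseline_subject A [subject_params()]: the cohort-average baseline.
#' @param treated_slopes,untreated_slopes Named lists of per-month drifts of
#'   the metric means for each group.
#' @param random_intercept_sd Named list of between-patient SDs of the
#'   baseline metric means.
#' @param severity Optional integer disease-severity scores (one per
#'   patient, clinical rating scale); carried as an opaque covariate.
#' @param seed Integer seed.
#'
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 9,
                          n_treated = 8,
                          followup_months_range = c(33, 61),
                          visit_interval_months_range = c(7, 12),
                          n_pretreatment_patients = 2,
                          n_pretreatment_visits = 2,
                          baseline_subject = subject_params(),
                          treated_slopes = list(isi_s = -0.001, gain = 0.001,
                                                latency_ms = -0.301),
                          untreated_slopes = list(isi_s = 0.026, gain = -0.004,
                                                  latency_ms = 0),
                          random_intercept_sd = list(isi_s = 0.08, gain = 0.05,
                                                     latency_ms = 20),
                          severity = c(5, 12, 7, 5, 11, 9, 6, 5, 4),
                          seed = 1) {
  known <- c("isi_s", "gain", "latency_ms", "vmax_dps", "error_prob")
  for (nm in list(treated_slopes, untreated_slopes, random_intercept_sd)) {
    bad <- setdiff(names(nm), known)
    if (length(bad) > 0) {
      abort(paste0("unknown metric name(s): ", paste(bad, collapse = ", "),
                   "; recognised: ", paste(known, collapse = ", ")),
            class = "sacclong_invalid_argument")
    }
  }
  stopifnot_msg(n_treated <= n_patients, n_patients >= 1,
                msg = "`n_treated` must not exceed `n_patients`")
  stopifnot_msg(diff(followup_months_range) >= 0,
                diff(visit_interval_months_range) >= 0,
                visit_interval_months_range[1] > 0,
                msg = "month ranges must be increasing and positive")
  stopifnot_msg(n_pretreatment_patients <= n_treated,
                msg = "`n_pretreatment_patients` must not exceed `n_treated`")
  sev <- rep(NA_integer_, n_patients)
  if (!is.null(severity)) {
    sev[seq_len(min(n_patients, length(severity)))] <-
      as.integer(severity[seq_len(min(n_patients, length(severity)))])
  }
  structure(
    list(n_patients = as.integer(n_patients),
         n_treated = as.integer(n_treated),
         followup_months_range = followup_months_range,
         visit_interval_months_range = visit_interval_months_range,
         n_pretreatment_patients = as.integer(n_pretreatment_patients),
         n_pretreatment_visits = as.integer(n_pretreatment_visits),
         baseline_subject = baseline_subject,
         treated_slopes = treated_slopes,
         untreated_slopes = untreated_slopes,
         random_intercept_sd = random_intercept_sd,
         severity = sev,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

# metric name -> subject_params field
metric_field <- c(isi_s = "selfpaced_isi_mean_s", gain = "gain_mean",
                  latency_ms = "latency_mean_ms", vmax_dps = "vmax",
                  error_prob = "antisaccade_error_prob")

#' Simulate a longitudinal patient cohort
#'
#' Draws a visit schedule and per-visit ground-truth oculomotor parameters
#' for every patient. Each patient receives a baseline parameter set
#' perturbed by per-metric random intercepts; each metric mean then drifts
#' linearly in months at its group's slope. Treated patients are followed in
#' months since treatment onset; the never-treated patient's clock is months
#' since first visit. Pre-treatment visits of treated patients are labelled
#' `untreated` and drift at the untreated slope.
#'
#' @param config A [cohort_config()].
#' @param level `"params"` returns the manifest and ground-truth per-visit
#'   parameters; `"trials"` additionally draws trial-level observations
#'   (per-trial ISIs, gains and latencies) from each visit's parameters,
#'   without simulating waveforms; `"traces"` additionally simulates full
#'   gaze traces for every visit and task.
#' @param tasks Tasks recorded at each visit (used for `level = "traces"`).
#' @param protocols Optional named list of [task_protocol()] objects
#'   overriding the per-task defaults (e.g. shorter sessions).
#' @param n_trials_per_visit For `level = "trials"`: how many gain/latency
#'   observations to draw per visit (ISI draws follow the 30-s task length).
#'
#' @return An object of class `saccade_cohort`: a list with `manifest`
#'   (patient_id, session_id, months, months_since_onset, group, severity),
#'   `visit_params` (ground-truth [subject_params()] fields per visit),
#'   optionally `trials` (long tibble: patient_id, session_id, months,
#'   group, metric, value) and `sessions` (named list of
#'   [simulate_session()] results per visit and task), and `config`.
#' @export
#' @examples
#' coh <- simulate_cohort(cohort_config(seed = 42))
#' table(coh$manifest$group[!duplicated(coh$manifest$patient_id)])
simulate_cohort <- function(config,
                            level = c("params", "trials", "traces"),
                            tasks = c("prosaccade", "antisaccade", "selfpaced"),
                            protocols = NULL,
                            n_trials_per_visit = 55) {
  stopifnot_msg(inherits(config, "cohort_config"),
                msg = "`config` must be a cohort_config()")
  level <- match.arg(level)
  set.seed(config$seed)

  np <- config$n_patients
  n_untreated <- np - config$n_treated
  untreated_ids <- if (n_untreated == 0) {
    integer(0)
  } else if (n_untreated == 1 && np >= 5) {
    5L                                  # patient #5 untreated throughout
  } else {
    seq.int(np - n_untreated + 1L, np)
  }
  treated_ids <- setdiff(seq_len(np), untreated_ids)
  pretreat_ids <- head(treated_ids, config$n_pretreatment_patients)

  metrics <- union(names(config$treated_slopes),
                   union(names(config$untreated_slopes),
                         names(config$random_intercept_sd)))
  base <- config$baseline_subject

  manifest <- list(); vparams <- list()
  for (pid in seq_len(np)) {
    treated <- pid %in% treated_ids
    f <- runif(1, config$followup_months_range[1],
               config$followup_months_range[2])
    gaps <- runif(15, config$visit_interval_months_range[1],
                  config$visit_interval_months_range[2])
    m <- c(0, cumsum(gaps))
    m <- m[m <= f]
    if (treated && pid %in% pretreat_ids) {
      pre <- -rev(cumsum(runif(config$n_pretreatment_visits,
                               config$visit_interval_months_range[1],
                               config$visit_interval_months_range[2])))
      m <- c(pre, m)
    }
    b <- vapply(metrics, function(mm) {
      s <- config$random_intercept_sd[[mm]] %||% 0
      rnorm(1, 0, s)
    }, numeric(1))

    for (vi in seq_along(m)) {
      mo <- m[vi]
      grp <- if (treated && mo >= 0) "treated" else "untreated"
      p <- unclass(base)
      for (mm in metrics) {
        slope <- if (treated && mo >= 0) {
          config$treated_slopes[[mm]] %||% 0
        } else {
          config$untreated_slopes[[mm]] %||% 0
        }
        fld <- metric_field[[mm]]
        p[[fld]] <- p[[fld]] + b[[mm]] + slope * mo
      }
      # keep the drifted parameters physically admissible
      p$selfpaced_isi_mean_s <- max(p$selfpaced_isi_mean_s, 0.2)
      p$gain_mean <- max(p$gain_mean, 0.3)
      p$latency_mean_ms <- max(p$latency_mean_ms, 100)
      p$vmax <- max(p$vmax, 50)
      p$antisaccade_error_prob <- min(max(p$antisaccade_error_prob, 0), 1)
      clock <- if (treated) mo else mo - min(m)
      if (!treated) clock <- mo            # never-treated: since first visit
      if (grp == "untreated" && treated) clock <- mo - min(m)
      manifest[[length(manifest) + 1L]] <- tibble(
        patient_id = pid,
        session_id = sprintf("P%02d_V%02d", pid, vi),
        months = clock,
        months_since_onset = if (treated) mo else NA_real_,
        group = grp,
        severity = config$severity[pid]
      )
      vparams[[length(vparams) + 1L]] <-
        tibble(session_id = sprintf("P%02d_V%02d", pid, vi),
               !!!p[names(p) != "class"])
    }
  }
  manifest <- bind_rows(manifest)
  vparams <- bind_rows(vparams)

  out <- structure(list(manifest = manifest, visit_params = vparams,
                        config = config),
                   class = "saccade_cohort")
  if (level == "params") return(out)

  if (level == "trials") {
    out$trials <- draw_cohort_trials(manifest, vparams, base,
                                     n_trials_per_visit)
    return(out)
  }

  # level == "traces": simulate full sessions
  protos <- list(
    prosaccade = task_protocol("prosaccade"),
    antisaccade = task_protocol("antisaccade"),
    selfpaced = task_protocol("selfpaced")
  )
  for (nm in names(protocols %||% list())) protos[[nm]] <- protocols[[nm]]
  sessions <- list()
  for (i in seq_len(nrow(manifest))) {
    vp <- vparams[i, ]
    subj <- do.call(subject_params,
                    as.list(vp[names(vp) != "session_id"]))
    for (tk in tasks) {
      sd_i <- sample.int(.Machine$integer.max, 1)
      key <- paste0(manifest$session_id[i], "_", tk)
      sessions[[key]] <- simulate_session(protos[[tk]], subj, seed = sd_i)
    }
  }
  out$sessions <- sessions
  out
}

draw_cohort_trials <- function(manifest, vparams, base, n_trials) {
  rows <- list()
  for (i in seq_len(nrow(manifest))) {
    vp <- vparams[i, ]
    n_isi <- max(3L, round(30 / vp$selfpaced_isi_mean_s) - 1L)
    isi <- rgamma(n_isi, shape = vp$selfpaced_isi_shape,
                  scale = vp$selfpaced_isi_mean_s / vp$selfpaced_isi_shape)
    gain <- rnorm(n_trials, vp$gain_mean, vp$gain_sd)
    lat <- draw_latencies(n_trials, vp$latency_mean_ms, vp$latency_sd_ms)
    rows[[i]] <- tibble(
      patient_id = manifest$patient_id[i],
      session_id = manifest$session_id[i],
      months = manifest$months[i],
      group = manifest$group[i],
      metric = rep(c("isi_s", "gain", "latency_ms"),
                   times = c(n_isi, n_trials, n_trials)),
      value = c(isi, gain, lat)
    )
  }
  bind_rows(rows)
}

#' @export
print.saccade_cohort <- function(x, ...) {
  cat("<saccade_cohort>", x$config$n_patients, "patients,",
      x$config$n_treated, "treated;", nrow(x$manifest), "visits\n")
  invisible(x)
}
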