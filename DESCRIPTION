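Package: sacclong
Title: Saccade Metrics and Longitudinal Mixed-Effects Trajectories from
    Gaze Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for longitudinal saccadometry: simulate 1 kHz gaze-position
    recordings for prosaccade, antisaccade and self-paced saccade tasks with
    known ground truth, detect saccades with a velocity-threshold algorithm,
    compute per-session oculomotor metrics (gain, latency, main-sequence
    asymptotic peak velocity, HSEM-alpha, antisaccade error rate, self-paced
    saccade count and inter-saccadic interval), build proportional
    change-from-baseline scores, and fit treated-versus-untreated linear
    mixed-effects trajectories with patient-varying intercepts. Designed for
    small clinical cohorts followed over months to years, such as
    Niemann-Pick Type C patients on substrate-reduction therapy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    lme4,
    minpack.lm,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
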