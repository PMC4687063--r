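---
title: "Saccadometry and longitudinal trajectories with sacclong"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Saccadometry and longitudinal trajectories with sacclong}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sacclong)
```

## The problem

Horizontal saccades are a practical window on neurodegeneration: their
peak velocity is set by brainstem burst neurons, their accuracy (gain) by
parietal and cerebellar circuits, and volitional control (antisaccades,
self-paced refixations) by frontal networks. In slowly progressing
conditions such as Niemann-Pick Type C disease, per-session saccadic
metrics tracked over years of treatment can serve as objective efficacy
markers. `sacclong` implements that whole chain: it simulates 1 kHz gaze
recordings with known ground truth, detects saccades, computes the
standard per-session metrics, and fits treated-versus-untreated
trajectories with linear mixed-effects (LME) models.

Because raw patient recordings in this field are essentially never
deposited, the package treats its synthetic cohort generator as a
first-class, tested module: every downstream stage is validated by
recovering known generating parameters.

## The measurement model

**Main sequence.** Peak velocity saturates with amplitude as

$$V = V_{max}\,\bigl(1 - e^{-A/k}\bigr),$$

with $V_{max}$ (deg/s) the asymptotic peak velocity and $k$ (deg) the
amplitude constant. `fit_main_sequence()` estimates both by bounded
Levenberg-Marquardt least squares, initialised at the maximum observed
peak velocity and $k_0 = 10$ deg, with bounds $V_{max} \in (0, 2000]$,
$k \in (0, 100]$. Fits with fewer than 10 saccades or a single distinct
amplitude are flagged non-identifiable rather than guessed at.

**Peak duration and HSEM-α.** Peak duration is $PD = |A|/V$ (s). HSEM-α
is the ordinary-least-squares slope of $PD$ on $|A|$, with the intercept
reported alongside. When peak velocity is fully saturated,
$PD = A/V_{max}$ exactly and the slope equals $1/V_{max}$; over a finite
working range (say 15-30 deg with $k = 8$) the exponential still bends
the curve, and the slope-times-$V_{max}$ product computes to about 0.87
rather than 1. The package reports the product as computed; the inverse
relation should be read as asymptotic, not exact.

**Gain and latency.** Gain is the signed ratio of saccade amplitude to
target step; latency is onset time minus step time. Sessions are
summarised by mean gain and *median* latency — the latency distribution
has a long right tail, and the median is robust to it. Both trial-level
streams are kept for the LME stage.

**Antisaccade error rate.** The percentage of scoreable trials whose
primary saccade went toward the target. Trials with no qualifying
response are excluded from the denominator (whether the original clinical
protocols included them is typically unstated; the choice is recorded in
the output metadata by construction, since `n_scoreable` is returned).

**Self-paced saccades.** The count of refixations (amplitude at least
half the target separation) in a 30-s window, plus the inter-saccadic
intervals (ISI) between them, which give the trial-level stream for the
LME stage.

## Signal processing choices

Traces are differentiated with a zero-phase Savitzky-Golay filter (cubic,
23 ms window at 1 kHz, roughly a 50-60 Hz cutoff). The window is a
compromise measured on the generator: at 23 ms the filter attenuates the
peak velocity of even a 2.5 deg saccade by under 1.5%, while the velocity
noise floor at the tracker's 0.1 deg RMS noise stays near 7 deg/s — far
enough below the 50 deg/s detection threshold that noise-only traces
yield no events (tested up to 0.2 deg RMS).

Detection uses conventional oculomotor thresholds, all configurable in
`saccade_thresholds()`: 50 deg/s peak threshold, 10 deg/s onset/offset
refinement, 1 deg minimum amplitude, 50 ms minimum separation (closer
events are merged). Amplitude is measured as the change in smoothed
position across the event, averaged over an 8 ms flanking window on each
side to suppress endpoint noise.

Two refinements matter for unbiased timing. First, the 10 deg/s crossing
systematically lags the true onset (a smooth velocity ramp spends several
ms below threshold — up to ~5.6 ms for a 30 deg saccade), so the
reported onset and offset are extrapolated from an anchor at 25% of the
event's peak speed, where the flank is steep and noise relatively small.
Near its foot a smooth unimodal profile rises quadratically, which puts
the true boundary at $c\,v/\dot v$ before the anchor with $c = 2$ for an
exact parabola; the cosine flank at quarter-peak and the smoothing filter
both shrink the effective constant, and $c = 1.7$ centres the onset error
at zero (SD ≈ 2 ms) on simulated sessions. Event *boundaries* used for
amplitude and peak-velocity measurement remain the threshold crossings.
Second, trial pairing uses an 80-700 ms response window: faster responses
are marked anticipatory and excluded from latency/gain summaries, absent
responses are marked `no_response`, and the minimum response amplitude is
half the smallest target step (2.5 deg for prosaccades, 2 deg for
antisaccades) so corrective microsaccades are never paired with a step.

## The synthetic cohort generator

`simulate_session()` emulates the three tasks as run in longitudinal
clinical saccadometry:

* prosaccades: 60 pseudo-random horizontal jumps, magnitudes uniform on
  5-30 deg, no more than four consecutive same-direction steps, target
  kept within ±30 deg (the published protocols state the range and
  "pseudo-random" order but not the exact sequence; the run-length cap is
  a plausible reading, and the amplitude draw is truncated near the
  position bound);
* antisaccades: 39 presentations at ±5 and ±10 deg with a return to
  fixation between trials; the primary response goes toward the target
  with the subject's error probability;
* self-paced: alternating refixations between targets at ±10 deg with
  gamma-distributed ISIs (a positive, right-skewed family; the
  distributional form is a modelling choice, as sources report only
  summaries), floored at a 150 ms refractory interval, for 30 s.

Saccade waveforms use a symmetric raised-cosine velocity profile, so
duration is exactly $2|A|/V_{peak}$ and the generated peak velocities lie
exactly on the main sequence before noise — which is what makes detector
recovery exactly testable. Latencies are log-normal (mean 250 ms, SD
50 ms by default) truncated to the 80-700 ms response window; gains are
normal (0.85 ± 0.08, hypometric as in impaired cohorts); measurement
noise is additive white Gaussian at 0.1 deg RMS, matching the stated
sensitivity of infrared limbus trackers; the fixation interval between
trials is uniform 1.2-1.8 s (unreported in the sources; configurable).
The default antisaccade error probability is 0.7, reflecting the
near-floor performance of symptomatic adult patients.

`simulate_cohort()` layers the longitudinal structure on top: nine
patients (eight treated, one never treated; two of the treated recorded
twice before treatment onset), follow-up 33-61 months at 7-12 month
intervals, per-patient random intercepts on each metric, and linear
per-month drifts of the metric means with group-specific slopes. The
default slopes take published per-month fixed effects for a treated and
an untreated group as generative truth: ISI −0.001 vs +0.026 s/month,
gain +0.001 vs −0.004 per month, latency −0.301 ms/month treated and
flat untreated. Treated patients are followed in months since treatment
onset; pre-treatment visits are labelled untreated and drift at the
untreated slope (so trajectories are continuous at onset); the
never-treated patient's clock is months since first visit. Between-patient
intercept SDs (0.08 s ISI, 0.05 gain, 20 ms latency) are chosen to give
visible but not overwhelming heterogeneity, typical of small clinical
cohorts.

What the generator does *not* emulate: blinks and tracker artifacts,
corrective secondary saccades, drift and square-wave jerks, express
saccades, fatigue trends within a session, and any vertical component.
Passing recovery tests therefore certify the pipeline's correctness under
clean-but-noisy recordings, not its robustness to artifact-laden clinical
data — artifact handling would need its own validation against real
recordings.

## Longitudinal analysis

`change_from_baseline()` expresses each visit as a proportional change
from the patient's baseline (first visit at or after month zero). The
improvement direction is metric-specific (`metric_orientation()`):
increases are improvements for gain, $V_{max}$ and self-paced count;
decreases for HSEM-α, latency, antisaccade error rate and ISI. A zero or
missing baseline flags the patient-metric series rather than producing
infinities.

`fit_saccade_lme()` fits, per metric, one model per group
(`value ~ months + (1 | patient)`) and a combined model with a
months-by-group interaction. Random intercepts only: with a handful of
patients, random slopes are rarely identifiable, and intercept-only
matches the published modelling this package emulates. Trial-level rows
(ISI, gain, latency) feed the models; antisaccade error rate and
self-paced count are single numbers per session and are analysed
descriptively through change scores only. p values are Wald t statistics
with residual degrees of freedom, recorded as such in the output —
`lme4` deliberately reports none, and with thousands of trial-level rows
the Wald test is effectively a z test; simulations with both slopes zero
put its interaction type-I error at the nominal 5% (±2%) level. Missing
visits are simply absent rows; no imputation.

Monte-Carlo checks in the test suite show that with the default cohort
(nine patients) and the generative slopes above, the fitted treated and
untreated ISI slopes recover their signs and the interaction reaches
p < .05 in well over 90% of replicates — the package's stand-in for
results whose patient-level data cannot be reproduced.

## Numerical and degenerate-input policy

* Main-sequence and HSEM-α fits require ≥ 10 saccades spanning ≥ 2
  distinct amplitudes; otherwise they return flagged, `NA`-valued results
  instead of errors, so one bad session never aborts a cohort run.
* A failed or boundary nonlinear fit is retried once from a perturbed
  start, then flagged.
* Zero target steps in a stimulus-driven trace, a zero step amplitude,
  or a zero-length trace raise classed errors (`sacclong_invalid_*`).
* All randomness flows from explicit integer seeds; the same seed
  reproduces traces, manifests and metric CSVs byte for byte, which the
  pipeline's run manifest verifies with MD5 checksums.

## Problem sizes used in validation

The shipped tests run the validation at the study's own scale: 60-trial
prosaccade sessions; 50-session detection round-trips; 200 replicates for
parameter recovery (bias < 2% on gain, latency, antisaccade error
probability and ISI mean); 200 simulated cohorts for LME sign/power and
500 for type-I error; 500 replicates for the $V_{max}$
confidence-interval coverage check. `scripts/acceptance.R` recomputes the
same quantities at moderately reduced sizes (25 sessions, 100-250
replicates), recording each `n` alongside each value.

## Known limitations

* HSEM-α's inverse-$V_{max}$ correspondence is asymptotic; over a 15-30
  deg amplitude window the product $\alpha V_{max}$ is ≈ 0.87, and users
  comparing against $1/V_{max}$ should restrict to saturated amplitudes.
* The detector is tuned for 1 kHz recordings; it runs at ≥ 250 Hz but the
  boundary-refinement constants were validated at 1 kHz.
* Wald p values with residual df are anti-conservative for *session-level*
  rows with few patients; the package follows the trial-level design
  where that is immaterial, but session-level LME users should prefer the
  flagged output and their own df correction.
* The antisaccade generator produces a single primary response per trial;
  real patients produce corrective sequences whose scoring conventions
  vary between laboratories.
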