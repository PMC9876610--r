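---
title: "Methods: gaze preprocessing and trait-moderation inference in gazetraits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gaze preprocessing and trait-moderation inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazetraits)
```

## The scientific problem

`gazetraits` implements a complete analysis pipeline for free-viewing
eye-tracking studies of attention to the eye region of faces, and of how two
continuous traits — autistic traits (Autism-spectrum Quotient, AQ) and social
anxiety (Social Phobia Inventory, SPIN) — separately and interactively
modulate that attention. The design it targets is an emotion-discrimination
task: a peripheral fixation attractor, then a centrally presented face
(five emotions: angry, fearful, happy, sad, neutral) shown for 10 s while
binocular gaze is recorded at 300 Hz on a 1920 x 1080 screen, organised in
4 blocks of 20 trials for each of 60 participants.

Three temporal stages of eye-looking are distinguished, mirroring the
vigilance / maintenance / avoidance framework for attention to social
threat:

1. **Overall eye-looking** — eyes dwell time divided by total face dwell
   time (eyes + rest of face) over the whole trial.
2. **Initial attention** — whether the *first* on-face fixation lands on
   the eyes, and (when it does) its duration and its latency from face
   onset. Duration captures early attention maintenance; latency and the
   first-fixation proportion capture vigilance versus early avoidance.
3. **Temporal dynamics** — proportional eye-looking in 250-ms
   moving-average epochs across the 10 s, compared between high/low trait
   groups with a cluster-based permutation test.

## Preprocessing

Raw samples carry per-eye screen coordinates and validity flags.
The stages, in order:

* **Gap interpolation** (`interpolate_gaps()`): runs of invalid samples
  bounded by valid samples on both sides are filled by linear
  interpolation per coordinate, separately per eye, when the time gap
  between the bounding valid samples is at most 75 ms. Longer gaps and
  gaps touching a trial edge stay invalid. Valid samples are never
  altered, so the valid-sample count is non-decreasing.
* **Binocular averaging** (`merge_binocular()`): both eyes valid gives
  the coordinate mean; exactly one valid eye is used as-is (this
  maximizes data retention; dropping one-eyed samples is the obvious
  alternative and would only shrink the valid fraction); neither valid
  gives an invalid cyclopean sample.
* **Fixation detection** (`detect_fixations()`): a dispersion-based
  algorithm (I-DT). Fixations are maximal sample windows whose dispersion
  (x range + y range) stays within a threshold, kept when their duration
  reaches a minimum. Defaults: dispersion of one degree of visual angle
  (about 37.9 px for a 531-mm-wide, 1920-px screen viewed at 60 cm — the
  physical screen size is an assumption and every constant is
  configurable) and 60 ms minimum duration. I-DT was chosen because it is
  deterministic and directly checkable against a brute-force
  window-growing oracle, which the test suite does on hundreds of random
  traces; a velocity-threshold variant (I-VT, 30 deg/s default) is
  available as `method = "ivt"`. Invalid samples break windows. Offsets
  are exclusive (last sample time plus one sample period), so a k-sample
  window has duration k periods.
* **AOI assignment** (`assign_aoi()`): the face AOI is a centred square
  subtending 20 x 20 degrees (the stimulus size); the eyes AOI is a
  full-width band from 25% to 45% of face height, covering both eyes
  jointly. Membership is tested on the fixation centroid with half-open
  rectangles `[x0, x1) x [y0, y1)`, so a centroid exactly on the
  right/bottom edge falls outside. Real studies should measure their AOIs
  on their stimuli and pass them in; the defaults exist so the simulator
  and the preprocessing share one geometry.
* **Trial validity** (`validate_trial()`): a trial is excluded when more
  than 30% of its post-interpolation samples are missing, when less than
  50% of the trial is spent looking at the face (computed from fixation
  time by default; a sample-based variant is available since it is not
  knowable which a given lab used), or when the behavioural response was
  incorrect. Thresholds are strict inequalities: exactly 30% missing and
  exactly 50% face time is still valid. Reasons are recorded
  non-exclusively so either accounting order can be reconstructed.

## Questionnaire scoring and grouping

The AQ has 50 four-point items (1 = definitely disagree ... 4 = definitely
agree). Under the 4-point system, agree-keyed items score their response
and reverse-keyed items score 5 minus it (total 50-200); under the
dichotomous system each item scores 1 when endorsed in its keyed direction
(total 0-50). The standard published agree-key (24 items) ships as a
plain-text config file and can be replaced. The SPIN has 17 items scored
0-4 (total 0-68). Missing items are an error — no imputation.

For the mixed models, the 4-point AQ and SPIN totals are z-standardized
over the post-exclusion analysis sample (the sample entering the models,
not the recruited sample). For the temporal analysis, participants are
split at the conventional screening cutoffs: dichotomous AQ >= 26 and
SPIN >= 19 define the high groups. `trait_levels_from_moments()` maps
z-levels back to original-scale scores for reporting (with the target
cohort's moments, -1/0/+1 SD correspond to AQ scores 106, 120 and 135).

## Inference

**Mixed models.** Each dependent variable is analysed with
`response ~ z_aq4 * z_spin * emotion + sex + (1 | participant)`, fitted
by REML through `lme4`/`lmerTest`. Emotion (and the sex covariate) are
sum-to-zero coded so Type III F tests are meaningful; denominator degrees
of freedom use the Satterthwaite approximation (Kenward-Roger optional
where `pbkrtest` is available). The random structure is an intercept per
participant; random emotion slopes are deliberately not offered as a
default because with 16 trials per emotion per participant they routinely
fail to converge on data of this shape. Four models are fitted: overall
eye proportion (all valid trials), the trial-level first-fixation-on-eyes
indicator (a linear probability model, which keeps the moderation
analysis on one scale across outcomes), and the natural-log first-fixation
duration and latency on the subset of trials whose first on-face fixation
was on the eyes. Logs are natural; the base only rescales coefficients.

**Simple slopes.** The conditional slope of `z_spin` at moderator levels
`z_aq4 = a` (-1, 0, +1 SD, labelled low/medium/high autistic traits) is
`B = b_spin + a * b_interaction`, marginal over emotion thanks to the
sum coding; its SE and Satterthwaite df come from the coefficient
covariance via a single-contrast test, and the standardized slope is
`beta = B * SD(z_spin) / SD(response)` over the analysis sample. The
test suite verifies the slopes against refits with the moderator
recentred at each level (agreement to 1e-8). Pairwise slope differences
between levels, optionally within each emotion, are Wald tests on the
corresponding contrast; the procedure behind published per-emotion slope
comparisons is not standardized, so this is an explicit interpretation.

**Cluster-based permutation test.** Participant-level epoch curves
(mean over that participant's valid trials of eyes / (eyes + face) time
per 250-ms window) are compared between two groups with a per-epoch
Welch t statistic; undefined epoch values (windows with no face time)
are excluded pairwise rather than imputed. Epochs with |t| above the
two-sided critical value at the cluster-forming alpha (0.05) form
maximal contiguous same-sign clusters scored by their summed t. The null
distribution of the maximum absolute cluster mass is built by relabeling
participants: exhaustively when the relabeling space has at most 1e5
elements, otherwise with 1000 seeded random relabelings, and Monte-Carlo
p-values use the add-one convention `p = (1 + #{null >= observed}) /
(1 + n_perm)`, which keeps the test level-valid at any permutation
count. Welch was preferred over the pooled-variance t because the trait
groups are unequal by construction (cutoff splits).

**Moving-average step.** The epoch window is 250 ms; the step defaults
to 50 ms (overlapping windows) for smooth curves and is configurable
down to per-sample. The simulation-heavy test suites use a 250-ms step
(non-overlapping) since their calibration and power properties do not
depend on the step.

## The synthetic-data generator

`gen_dataset()` is a forward model of the whole study, not a test
fixture: cohort, trial design, AOI-level fixation schedules, and
rasterized 300 Hz binocular samples, with every latent quantity recorded
as ground truth.

* **Cohort**: (AQ4, SPIN) from a bivariate normal with target correlation
  0.44 and the target study's moments (AQ4 120.35 +/- 14.28, SPIN 24.37
  +/- 12.47), rounded and clipped to the scale ranges; the dichotomous AQ
  derives from the 4-point total by the calibrated monotone map
  `round((aq4 - 50) / 3)`, which maps the scale endpoints onto each other
  and reproduces the observed pairing of means (about 23 dichotomous at
  120 four-point). Age, sex and judgment accuracy (0.885) match the
  target cohort.
* **Trial schedule**: a semi-Markov AOI process quantized to the sample
  grid. Each trial starts with a latency period at the peripheral
  fixation location (log-normal latency), then a first on-face fixation
  that lands on the eyes with trait-dependent probability (logit scale),
  then alternating fixations on eyes / rest-of-face / off-screen with
  trait-dependent transition probabilities and gamma dwell times. The
  latency and the first eyes-fixation duration are log-normal because the
  downstream models analyse their logs (empirically these quantities are
  right-skewed); no distributional information beyond non-normality is
  available for the target data, so these families are stated modelling
  choices, not facts. Trait effects enter linearly on the log/logit
  scales with an AQ x SPIN product term, which makes parameter-recovery
  tests well-posed because the generative model matches the fitted one.
  Segment durations are integer sample counts summing exactly to 3000,
  so ground-truth dwell conservation is exact and noise-free round-trip
  recovery can match durations to within one sample period.
* **Default effect directions** encode the phenomena the pipeline is
  meant to detect, at magnitudes chosen by power arithmetic before any
  test was run: SPIN slope on log first-fixation duration of 0.25 at
  +1 SD AQ and 0 at -1 SD (b_spin = b_int = 0.125, residual SD 0.45);
  a first-fixation-on-eyes logit interaction of -0.35; a log-latency
  interaction of +0.08; and a late-window (after 5 s) eyes-transition
  logit decrement of 1.5 per SD of AQ. Calibration suites switch all of
  them off explicitly.
* **Noise and missingness**: the cyclopean path gets iid coordinate
  noise (2.5 px) within fixations; each eye adds independent 2-px noise.
  Tracking losses are Poisson bursts (0.25/s, exponential mean 60 ms);
  7% of trials suffer degraded tracking (25x burst rate, 3x duration),
  which typically crosses the 30%-missing exclusion — emulating the
  realistic bursty loss and the roughly one-in-six invalid-trial rate of
  desktop eye-tracking sessions. Saccades are instantaneous (the gaze
  point jumps between fixation targets): transit samples carry little
  analysable signal for dwell-based metrics, and omitting them keeps the
  schedule-to-fixation correspondence exact.
* **Determinism**: one global seed; per-participant and per-trial seeds
  are derived arithmetically from it, so any trial can be regenerated
  independently of generation order and identical parameters give
  byte-identical datasets.

What the generator does *not* emulate: saccade kinematics, smooth
pursuit, pupil size, head movement, calibration drift, emotion-specific
gaze differences beyond a configurable offset, and any dependence of
data quality on traits. Passing tests on this synthetic cohort therefore
demonstrate that the pipeline recovers the structure this model encodes —
not that real faces elicit that structure.

## Numerical and design choices

* Interpolation gap span is measured between the bounding valid samples
  (not the invalid run alone), matching the "maximum time gap" reading.
* Rectangle membership is half-open to make AOI labels a partition.
* The exclusion thresholds are strict inequalities; boundary trials are
  kept.
* Missing fraction is computed after interpolation over the full 10-s
  window, because interpolation precedes exclusion in the pipeline order.
* Degenerate inputs: empty traces yield empty fixation tables; trials
  with no on-face fixation yield NA metrics with a warning; fewer than
  two participants per group makes the cluster comparison refuse to run
  (recorded as skipped in the results bundle rather than crashing the
  battery); aliased fixed-effect columns are an error naming the columns;
  non-convergence is flagged on the result, never silent.
* Permutation p-values count ties with a 1e-10 relative tolerance so the
  observed relabeling always matches its own entry in the exact null.

## Problem sizes in the test and acceptance suites

The statistical suites run at reduced, stated sizes chosen to estimate
the relevant rates precisely enough while keeping the suite practical:
calibration uses 500 replicates of 20 participants x 20 trials under the
global null (both the Type III interaction test and the cluster test are
required to reject at 5% +/- 2%); directional recovery uses 100
replicates of 40 participants x 40 trials at the default effect sizes
(>= 80% required); oracle equivalence uses 500 random short traces and
exhaustive enumeration on 6-participant instances. These suites run the
pipeline from the generator's ground-truth AOI schedules; that shortcut
is licensed by the separate round-trip criterion showing sample-level
preprocessing reproduces those schedules exactly on noise-free data and
to within one sample period in duration.

## Known limitations

* The linear probability LMM on the first-fixation indicator inherits
  the usual caveats (heteroscedastic residuals, predictions outside
  [0, 1]); a logistic GLMM would be the natural alternative but changes
  the moderation scale and was not the target analysis.
* The generator's trait effects are homogeneous across emotions by
  default, so emotion-by-trait interactions in fitted models reflect
  noise unless offsets are configured.
* With cutoff-based group splits, small cohorts can produce degenerate
  groups; the battery records this instead of testing.
* Welch t on 20-trial mean proportions can be coarse in the earliest
  epochs where few trials contribute face time; pairwise exclusion
  handles the undefined values but power there is low.
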