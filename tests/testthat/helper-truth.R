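# Interval-level pipeline over the generator's ground-truth schedules:
# used by the statistical-calibration and direction-recovery suites, where
# rasterizing thousands of 300 Hz replicates would add nothing (sample-level
# recovery of the schedules is established separately by the round-trip
# tests).
truth_metrics <- function(d) {
  fx <- dataset_truth_fixations(d)
  man <- d$manifest
  val <- man[, c("participant_id", "block", "trial")]
  val$valid <- man$correct
  val$missing_gt_30pct <- FALSE
  val$face_lt_50pct <- FALSE
  val$incorrect_response <- !man$correct
  tm <- trial_metrics_table(fx, val)
  scored <- standardize_and_group(d$participants)
  trials <- merge(merge(tm, scored, by = "participant_id"),
                  man[, c("participant_id", "block", "trial", "emotion")],
                  by = c("participant_id", "block", "trial"))
  list(fixations = fx, validity = val, trials = trials, scored = scored)
}

quiet_lmm <- function(...) {
  suppressWarnings(suppressMessages(fit_gaze_lmm(...)))
}
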