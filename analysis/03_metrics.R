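#!/usr/bin/env Rscript
# Score traits and compute the dependent variables: overall proportional
# eye-looking time, first-fixation indicator/duration/latency (with log
# transforms), per-participant first-fixation proportions, and the 250-ms
# moving-average eye-looking time courses.

suppressMessages({
  library(gazetraits)
  library(optparse)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--data", type = "character", default = "scratch/gaze_data"),
  make_option("--derived", type = "character", default = "scratch/derived")
)))

dir.create("results", showWarnings = FALSE)
ds <- read_dataset(opts$data)
fixations <- data.table::fread(file.path(opts$derived, "fixations.csv"))
validity <- data.table::fread(file.path(opts$derived, "validity.csv"))
config <- default_config()

scored <- standardize_and_group(ds$participants,
                                aq_cutoff = config$groups$aq_cutoff,
                                spin_cutoff = config$groups$spin_cutoff)
tm <- trial_metrics_table(fixations, validity)
trials <- merge(merge(tm, scored, by = "participant_id"),
                ds$manifest[, c("participant_id", "block", "trial", "emotion")],
                by = c("participant_id", "block", "trial"))
data.table::fwrite(trials, file.path(opts$derived, "trial_metrics.csv"))

ffp <- participant_first_fix_proportion(tm)
data.table::fwrite(merge(ffp, scored, by = "participant_id"),
                   "results/participant_metrics.csv")

curves <- participant_epoch_curves(fixations, validity,
                                   window = config$epochs$window_ms,
                                   step = config$epochs$step_ms)
saveRDS(curves, file.path(opts$derived, "curves.rds"))
curves_long <- data.frame(
  participant_id = rep(rownames(curves$curves), ncol(curves$curves)),
  t_mid_ms = rep(curves$t_mid, each = nrow(curves$curves)),
  prop_eyes = as.vector(curves$curves))
data.table::fwrite(curves_long, "results/epoch_curves_long.csv")

message(sprintf("Valid trials: %d / %d", sum(trials$valid), nrow(trials)))
message(sprintf("Mean overall eye proportion (valid trials): %.3f",
                mean(trials$prop_eyes_overall[trials$valid], na.rm = TRUE)))
message(sprintf("First fixation on eyes: %.1f%% of valid trials",
                100 * mean(trials$first_fix_eyes[trials$valid], na.rm = TRUE)))
message(sprintf("Median latency to eyes: %.0f ms; median first duration: %.0f ms",
                median(trials$latency_to_eyes_ms, na.rm = TRUE),
                median(trials$first_fix_duration_ms, na.rm = TRUE)))
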