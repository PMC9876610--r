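#!/usr/bin/env Rscript
# Preprocess raw gaze samples into AOI-labelled fixations and trial
# validity: 75-ms gap interpolation, binocular averaging, I-DT fixation
# detection, AOI assignment, and the exclusion rules (>30% missing,
# <50% face time, incorrect response).

suppressMessages({
  library(gazetraits)
  library(optparse)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--data", type = "character", default = "scratch/gaze_data"),
  make_option("--out", type = "character", default = "scratch/derived")
)))

dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

ds <- read_dataset(opts$data)
config <- default_config()
message("Preprocessing ", length(unique(paste(ds$manifest$participant_id,
        ds$manifest$block, ds$manifest$trial))), " trials ...")
t0 <- Sys.time()
pp <- preprocess_dataset(ds$gaze, ds$manifest, config)
message(sprintf("done in %.1f s", as.numeric(Sys.time() - t0, units = "secs")))

data.table::fwrite(pp$fixations, file.path(opts$out, "fixations.csv"))
data.table::fwrite(pp$validity, file.path(opts$out, "validity.csv"))

ex <- exclusion_summary(pp$validity)
writeLines(jsonlite::toJSON(ex, auto_unbox = TRUE, pretty = TRUE),
           "results/exclusion_summary.json")
message(sprintf("Exclusions: %d of %d trials invalid (%.1f%%)",
                ex$n_invalid, ex$n_total, ex$pct_invalid))
message(sprintf("  missing>30%%: %d | face<50%%: %d | incorrect: %d",
                ex$reasons[["missing_gt_30pct"]],
                ex$reasons[["face_lt_50pct"]],
                ex$reasons[["incorrect_response"]]))
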