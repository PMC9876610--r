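#!/usr/bin/env Rscript
# Fit the analysis battery: four trait-moderation LMMs (overall eye
# proportion, first-fixation indicator, log first-fixation duration, log
# latency) with Satterthwaite Type III tests and simple slopes of social
# anxiety at -1/0/+1 SD of autistic traits, plus cluster-based permutation
# tests of the epoch time courses between trait groups.

suppressMessages({
  library(gazetraits)
  library(optparse)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--data", type = "character", default = "scratch/gaze_data"),
  make_option("--derived", type = "character", default = "scratch/derived"),
  make_option("--seed", type = "integer", default = 1L)
)))

dir.create("results", showWarnings = FALSE)
ds <- read_dataset(opts$data)
trials <- as.data.frame(
  data.table::fread(file.path(opts$derived, "trial_metrics.csv")))
curves <- readRDS(file.path(opts$derived, "curves.rds"))
config <- default_config(seed = opts$seed)

scored <- standardize_and_group(ds$participants,
                                aq_cutoff = config$groups$aq_cutoff,
                                spin_cutoff = config$groups$spin_cutoff)

message("Fitting LMMs and permutation tests ...")
t0 <- Sys.time()
bundle <- analyze_all(trials, scored, curves, config, seed = opts$seed)
message(sprintf("done in %.1f s", as.numeric(Sys.time() - t0, units = "secs")))

write_results_bundle(bundle, "results/results_bundle.json")
for (nm in c("prop_eyes_overall", "first_fix_eyes", "log_duration",
             "log_latency")) {
  data.table::fwrite(bundle[[nm]]$terms,
                     sprintf("results/lmm_terms_%s.csv", nm))
  data.table::fwrite(bundle[[nm]]$slopes,
                     sprintf("results/simple_slopes_%s.csv", nm))
}
report_bundle(bundle, "results/report.txt")
report_bundle(bundle)
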