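# End-to-end orchestration: dataset (in memory or on disk) -> fixations ->
# metrics -> inference bundle. The numbered scripts under analysis/ are
# thin drivers over these functions.

#' Read an on-disk gaze dataset
#'
#' Reads the delimited-text interface written by [gen_dataset()] (or
#' exported from a tracker in the same layout): `gaze.tsv`,
#' `manifest.csv`, `participants.csv`.
#'
#' @param dir dataset directory.
#' @return list with `gaze`, `manifest`, `participants`.
#' @export
read_dataset <- function(dir) {
  need <- file.path(dir, c("gaze.tsv", "manifest.csv", "participants.csv"))
  missing <- need[!file.exists(need)]
  if (length(missing)) {
    stop("missing dataset inputs: ", paste(basename(missing), collapse = ", "))
  }
  list(gaze = data.table::fread(need[1]),
       manifest = utils::read.csv(need[2]),
       participants = utils::read.csv(need[3]))
}

#' Run the full analysis pipeline
#'
#' Preprocesses every trial, scores and standardizes the participants over
#' the analysis sample, computes trial metrics and participant epoch
#' curves, and runs the full analysis battery ([analyze_all()]).
#'
#' When `fixations` are supplied directly (e.g. the generator's
#' ground-truth schedules via [schedule_fixations()]), preprocessing is
#' skipped and validity is derived from the manifest's `correct` flag
#' alone, since interval-level input carries no missingness.
#'
#' @param dataset list with `gaze`, `manifest`, `participants` (from
#'   [gen_dataset()] or [read_dataset()]).
#' @param config pipeline configuration, see [default_config()].
#' @param aois AOI geometry.
#' @param fixations optional precomputed AOI-labelled fixation table with
#'   trial identifiers, bypassing sample-level preprocessing.
#' @return list with `fixations`, `validity`, `trials` (metrics joined
#'   with traits and design), `participants` (scored), `curves`, `bundle`.
#' @export
run_pipeline <- function(dataset, config = default_config(),
                         aois = default_aois(), fixations = NULL) {
  man <- as.data.frame(dataset$manifest)
  if (is.null(fixations)) {
    pp <- preprocess_dataset(dataset$gaze, man, config, aois)
    fixations <- pp$fixations
    validity <- as.data.frame(pp$validity)
  } else {
    validity <- man[, c("participant_id", "block", "trial")]
    validity$valid <- man$correct
    validity$missing_fraction <- 0
    validity$face_fraction <- NA_real_
    validity$missing_gt_30pct <- FALSE
    validity$face_lt_50pct <- FALSE
    validity$incorrect_response <- !man$correct
  }
  tm <- trial_metrics_table(fixations, validity)
  # standardize over the analysis sample: participants with >= 1 valid trial
  scored <- standardize_and_group(as.data.frame(dataset$participants),
                                  aq_cutoff = config$groups$aq_cutoff,
                                  spin_cutoff = config$groups$spin_cutoff)
  trials <- merge(tm, scored, by = "participant_id")
  trials <- merge(trials,
                  man[, c("participant_id", "block", "trial", "emotion")],
                  by = c("participant_id", "block", "trial"))
  curves <- participant_epoch_curves(fixations, validity,
                                     window = config$epochs$window_ms,
                                     step = config$epochs$step_ms,
                                     duration_ms = config$trial$duration_ms)
  bundle <- analyze_all(trials, scored, curves, config, seed = config$seed)
  list(fixations = fixations, validity = validity, trials = trials,
       participants = scored, curves = curves, bundle = bundle)
}

#' Ground-truth fixation table for a generated dataset
#'
#' Stacks [schedule_fixations()] over every trial of a [gen_dataset()]
#' result, with trial identifier columns, ready for the metric functions
#' or for `run_pipeline(..., fixations = )`.
#'
#' @param dataset output of [gen_dataset()].
#' @return data.table of AOI-labelled ground-truth fixations.
#' @export
dataset_truth_fixations <- function(dataset) {
  rate <- dataset$params$sample_rate
  out <- vector("list", length(dataset$schedules))
  keys <- strsplit(names(dataset$schedules), "_")
  for (i in seq_along(out)) {
    k <- keys[[i]]
    out[[i]] <- cbind(
      data.frame(participant_id = k[1], block = as.integer(k[2]),
                 trial = as.integer(k[3])),
      schedule_fixations(dataset$schedules[[i]], sample_rate = rate))
  }
  data.table::rbindlist(out)
}

#' Plain-text report of a results bundle
#'
#' Renders the analysis battery as readable text: Type III term tables,
#' simple slopes per model, significant clusters (or an explicit absence
#' line), and the exclusion summary. Purely presentational; every number
#' comes from the bundle.
#'
#' @param bundle output of [analyze_all()].
#' @param file optional path; default prints to the console.
#' @return (invisibly) the report lines.
#' @export
report_bundle <- function(bundle, file = "") {
  fmt_terms <- function(tt) {
    paste0(sprintf("  %-22s F(%d, %.2f) = %.2f, p = %.4f",
                   tt$term, tt$df1, tt$df2, tt$F, tt$p), collapse = "\n")
  }
  fmt_slopes <- function(ss) {
    paste0(sprintf("  %-6s B = %+.4f, t(%.1f) = %+.3f, beta = %+.3f, p = %.4f",
                   ss$label, ss$B, ss$df, ss$t, ss$beta, ss$p), collapse = "\n")
  }
  fmt_cluster <- function(cl) {
    if (isTRUE(cl$skipped)) {
      return(paste0("  comparison not run: ", cl$reason))
    }
    if (nrow(cl$clusters) == 0) {
      return("  no significant clusters")
    }
    paste0(sprintf("  cluster %.0f-%.0f ms: mass = %.2f, p = %.4f",
                   cl$t_mid[cl$clusters$start], cl$t_mid[cl$clusters$end],
                   cl$clusters$mass, cl$clusters$p), collapse = "\n")
  }
  lines <- c()
  add <- function(...) lines <<- c(lines, ...)
  lmm_names <- c(prop_eyes_overall = "Overall proportional eye-looking time",
                 first_fix_eyes = "First fixation on the eyes (indicator)",
                 log_duration = "Log first-fixation duration (eyes-first trials)",
                 log_latency = "Log latency to the eyes (eyes-first trials)")
  for (nm in names(lmm_names)) {
    add(paste0("== ", lmm_names[[nm]], " =="),
        fmt_terms(bundle[[nm]]$terms),
        "  simple slopes of social anxiety by autistic-trait level:",
        fmt_slopes(bundle[[nm]]$slopes), "")
  }
  add("== Temporal dynamics: high vs low autistic traits ==",
      fmt_cluster(bundle$cluster_aq), "",
      "== Temporal dynamics: high vs low social anxiety ==",
      fmt_cluster(bundle$cluster_spin), "")
  ex <- bundle$exclusions
  add(sprintf("Exclusions: %d of %d trials invalid (%.1f%%)",
              ex$n_invalid, ex$n_total, ex$pct_invalid),
      sprintf("  by reason: missing>30%%: %d, face<50%%: %d, incorrect: %d",
              ex$reasons[["missing_gt_30pct"]], ex$reasons[["face_lt_50pct"]],
              ex$reasons[["incorrect_response"]]))
  writeLines(lines, con = if (nzchar(file)) file else stdout())
  invisible(lines)
}
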