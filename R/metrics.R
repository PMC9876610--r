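# Questionnaire scoring, trait standardization and grouping, and the
# trial-level / temporal eye-looking dependent variables.

#' Standard AQ scoring key
#'
#' Returns a logical vector of length 50: TRUE for items keyed in the
#' "agree" direction (an agree response indicates autistic traits), FALSE
#' for reverse-keyed items. Shipped as a plain-text config file so an
#' alternative key can be swapped in.
#'
#' @param path optional path to a CSV with columns `item`, `agree_keyed`.
#' @return logical vector of length 50.
#' @export
aq_default_key <- function(path = system.file("extdata", "aq_scoring_key.csv",
                                              package = "gazetraits")) {
  key <- utils::read.csv(path)
  stopifnot(nrow(key) == 50, all(c("item", "agree_keyed") %in% names(key)))
  as.logical(key$agree_keyed[order(key$item)])
}

#' Score the AQ questionnaire (both systems)
#'
#' Items are 4-point responses (1 = definitely disagree ... 4 = definitely
#' agree). Under the 4-point system, agree-keyed items score their response
#' and reverse-keyed items score 5 minus the response, summing to 50-200.
#' Under the dichotomous system each item scores 1 when endorsed in the
#' keyed direction (response 3-4 on agree-keyed items, 1-2 on
#' reverse-keyed items), summing to 0-50.
#'
#' @param items numeric matrix/data.frame, one row per respondent,
#'   50 columns of responses in 1..4.
#' @param key logical length-50 agree-key, see [aq_default_key()].
#' @return data.frame with `aq4` and `aq_binary`.
#' @export
score_aq <- function(items, key = aq_default_key()) {
  items <- as.matrix(items)
  if (ncol(items) != 50) stop("AQ requires 50 item columns")
  if (anyNA(items)) stop("missing AQ item responses (no imputation)")
  if (any(items < 1 | items > 4)) stop("AQ responses must lie in 1..4")
  stopifnot(length(key) == 50)
  directed <- sweep(items, 2, ifelse(key, 0, 5), function(x, o)
    ifelse(o == 0, x, o - x))
  data.frame(aq4 = as.integer(rowSums(directed)),
             aq_binary = as.integer(rowSums(directed >= 3)))
}

#' Score the SPIN questionnaire
#'
#' 17 items rated 0 (not at all) to 4 (extremely); the total (0-68) is the
#' item sum, higher meaning more social anxiety.
#'
#' @param items numeric matrix/data.frame with 17 columns of responses 0..4.
#' @return integer vector of totals.
#' @export
score_spin <- function(items) {
  items <- as.matrix(items)
  if (ncol(items) != 17) stop("SPIN requires 17 item columns")
  if (anyNA(items)) stop("missing SPIN item responses (no imputation)")
  if (any(items < 0 | items > 4)) stop("SPIN responses must lie in 0..4")
  as.integer(rowSums(items))
}

#' Standardize traits and assign cutoff groups
#'
#' Adds z-scores of the 4-point AQ and SPIN totals (standardized against
#' the sample passed in, normally the post-exclusion analysis sample) and
#' dichotomous group labels: `aq_group` is `high` when the dichotomous AQ
#' total is >= `aq_cutoff` (default 26), `spin_group` is `high` when the
#' SPIN total is >= `spin_cutoff` (default 19).
#'
#' @param participants data.frame with `aq4`, `aq_binary`, `spin`.
#' @param aq_cutoff,spin_cutoff group cutoffs.
#' @return the input with `z_aq4`, `z_spin`, `aq_group`, `spin_group` added.
#' @export
standardize_and_group <- function(participants, aq_cutoff = 26,
                                  spin_cutoff = 19) {
  if (nrow(participants) < 2) stop("need at least 2 participants")
  for (v in c("aq4", "spin")) {
    if (stats::sd(participants[[v]]) == 0) {
      stop("zero variance in ", v, "; cannot standardize")
    }
  }
  participants$z_aq4 <- as.numeric(scale(participants$aq4))
  participants$z_spin <- as.numeric(scale(participants$spin))
  participants$aq_group <- factor(
    ifelse(participants$aq_binary >= aq_cutoff, "high", "low"),
    levels = c("low", "high"))
  participants$spin_group <- factor(
    ifelse(participants$spin >= spin_cutoff, "high", "low"),
    levels = c("low", "high"))
  participants
}

#' Map z-score levels back to original-scale trait scores
#'
#' For reporting simple-slope moderator levels in original units:
#' returns `mean + z * sd` rounded to whole scores for each requested
#' z level (default -1, 0, +1 for low/medium/high).
#'
#' @param mean,sd sample mean and SD of the trait.
#' @param z_levels z-score levels.
#' @return named integer vector.
#' @export
trait_levels_from_moments <- function(mean, sd, z_levels = c(-1, 0, 1)) {
  out <- as.integer(round(mean + z_levels * sd))
  names(out) <- c("low", "medium", "high")[match(z_levels, c(-1, 0, 1))]
  out
}

#' Trial-level eye-looking metrics
#'
#' From one trial's AOI-labelled fixations: `prop_eyes_overall` is eyes
#' fixation time divided by total face fixation time (eyes + rest of face)
#' over the whole trial; the first face fixation is the earliest fixation
#' whose AOI is `eyes` or `face`. When that fixation is on the eyes,
#' `first_fix_eyes` is TRUE, `first_fix_duration_ms` is its duration,
#' `latency_to_eyes_ms` its onset (time from face onset), and natural-log
#' transforms of both are provided; otherwise duration and latency are NA.
#'
#' @param fixations AOI-labelled fixation table for one trial.
#' @return one-row data.frame.
#' @export
trial_gaze_metrics <- function(fixations) {
  eyes_t <- sum(fixations$duration_ms[fixations$aoi == "eyes"])
  face_t <- sum(fixations$duration_ms[fixations$aoi == "face"])
  prop <- if (eyes_t + face_t > 0) eyes_t / (eyes_t + face_t) else NA_real_
  on_face <- fixations[fixations$aoi %in% c("eyes", "face"), , drop = FALSE]
  if (nrow(on_face) == 0) {
    warning("trial has no on-face fixation; metrics undefined")
    return(data.frame(prop_eyes_overall = prop, first_fix_eyes = NA,
                      first_fix_duration_ms = NA_real_,
                      latency_to_eyes_ms = NA_real_,
                      log_duration = NA_real_, log_latency = NA_real_))
  }
  first <- on_face[which.min(on_face$onset_ms), ]
  hit <- first$aoi == "eyes"
  dur <- if (hit) first$duration_ms else NA_real_
  lat <- if (hit) first$onset_ms else NA_real_
  data.frame(prop_eyes_overall = prop,
             first_fix_eyes = hit,
             first_fix_duration_ms = dur,
             latency_to_eyes_ms = lat,
             log_duration = ifelse(hit & dur > 0, log(dur), NA_real_),
             log_latency = ifelse(hit & lat > 0, log(lat), NA_real_))
}

#' Per-trial metrics for a whole dataset
#'
#' Applies [trial_gaze_metrics()] to every trial of a combined fixation
#' table and joins the validity record.
#'
#' @param fixations fixation table with `participant_id`, `block`, `trial`.
#' @param validity per-trial validity table from [preprocess_dataset()].
#' @return data.frame, one row per trial.
#' @export
trial_metrics_table <- function(fixations, validity) {
  fx <- data.table::as.data.table(fixations)
  keys <- c("participant_id", "block", "trial")
  met <- fx[, trial_gaze_metrics(.SD), by = keys]
  val <- data.table::as.data.table(validity)
  out <- merge(val, met, by = keys, all.x = TRUE)
  # trials with no fixations at all have no metric rows; mark undefined
  as.data.frame(out)
}

#' Per-participant proportion of first fixations on the eyes
#'
#' The number of valid, correctly answered trials whose first on-face
#' fixation landed on the eyes, divided by that participant's number of
#' valid correct trials. Participants without any valid trial get NA and
#' are flagged.
#'
#' @param trial_metrics output of [trial_metrics_table()].
#' @return data.frame with `participant_id`, `n_valid`, `first_fix_prop`,
#'   `flagged`.
#' @export
participant_first_fix_proportion <- function(trial_metrics) {
  dt <- data.table::as.data.table(trial_metrics)
  out <- dt[, {
    v <- valid & !is.na(first_fix_eyes)
    n <- sum(v)
    list(n_valid = n,
         first_fix_prop = if (n > 0) mean(first_fix_eyes[v]) else NA_real_,
         flagged = n == 0)
  }, by = participant_id]
  as.data.frame(out)
}

# Overlap (ms) of each fixation with each time window; rows = fixations,
# cols = windows given by starts (width `window`).
interval_overlap <- function(onset, offset, starts, window) {
  lo <- outer(onset, starts, pmax)
  hi <- outer(offset, starts + window, pmin)
  ov <- hi - lo
  ov[ov < 0] <- 0
  ov
}

#' Moving-average proportional eye-looking time course
#'
#' Slides a `window`-ms window (default 250 ms) across the trial in steps
#' of `step` ms and computes, per window, eyes fixation time divided by
#' total face fixation time within the window (from fixation-interval
#' overlap). Windows with no face-looking are NA.
#'
#' @param fixations AOI-labelled fixation table for one trial.
#' @param window window width in ms.
#' @param step step between window starts in ms.
#' @param duration_ms trial duration.
#' @return data.frame with `t_start`, `t_mid`, `value`.
#' @export
epoch_timecourse <- function(fixations, window = 250, step = 50,
                             duration_ms = 10000) {
  starts <- seq(0, duration_ms - window, by = step)
  eyes <- fixations$aoi == "eyes"
  face <- fixations$aoi == "face"
  ov <- interval_overlap(fixations$onset_ms, fixations$offset_ms,
                         starts, window)
  eyes_t <- colSums(ov[eyes, , drop = FALSE])
  face_t <- colSums(ov[face, , drop = FALSE])
  tot <- eyes_t + face_t
  value <- ifelse(tot > 0, eyes_t / tot, NA_real_)
  data.frame(t_start = starts, t_mid = starts + window / 2, value = value)
}

#' Participant-level epoch curves
#'
#' Computes the epoch time course for every valid trial and averages
#' within participant (NA epochs omitted per window). Returns a matrix of
#' participants x epochs, the layout the cluster-based permutation test
#' consumes.
#'
#' @param fixations combined AOI-labelled fixation table.
#' @param validity per-trial validity table.
#' @param window,step,duration_ms see [epoch_timecourse()].
#' @return list: `curves` (matrix, rownames = participant ids),
#'   `t_mid` (epoch centre times).
#' @export
participant_epoch_curves <- function(fixations, validity, window = 250,
                                     step = 50, duration_ms = 10000) {
  starts <- seq(0, duration_ms - window, by = step)
  fx <- data.table::as.data.table(fixations)
  val <- data.table::as.data.table(validity)
  keys <- c("participant_id", "block", "trial")
  fx <- merge(fx, val[, c(keys, "valid"), with = FALSE], by = keys)
  fx <- fx[valid == TRUE & aoi %in% c("eyes", "face")]
  ids <- sort(unique(val[valid == TRUE, participant_id]))
  curves <- matrix(NA_real_, nrow = length(ids), ncol = length(starts),
                   dimnames = list(ids, NULL))
  for (i in seq_along(ids)) {
    f <- fx[participant_id == ids[i]]
    if (nrow(f) == 0) next
    ov <- interval_overlap(f$onset_ms, f$offset_ms, starts, window)
    trial_key <- paste(f$block, f$trial)
    eyes_ov <- ov * (f$aoi == "eyes")
    eyes_t <- rowsum(eyes_ov, trial_key)
    tot_t <- rowsum(ov, trial_key)
    prop <- ifelse(tot_t > 0, eyes_t / tot_t, NA_real_)
    curves[i, ] <- colMeans(prop, na.rm = TRUE)
  }
  curves[is.nan(curves)] <- NA_real_
  list(curves = curves, t_mid = starts + window / 2)
}

#' Summarize trial exclusions
#'
#' Counts invalid trials overall and per (non-exclusive) reason, and
#' reports the overall invalid percentage rounded to one decimal.
#'
#' @param validity per-trial validity table.
#' @return list with `n_total`, `n_invalid`, `pct_invalid`, `reasons`.
#' @export
exclusion_summary <- function(validity) {
  v <- as.data.frame(validity)
  n <- nrow(v)
  inv <- sum(!v$valid)
  list(n_total = n,
       n_invalid = inv,
       pct_invalid = if (n > 0) round(100 * inv / n, 1) else NA_real_,
       reasons = c(missing_gt_30pct = sum(v$missing_gt_30pct),
                   face_lt_50pct = sum(v$face_lt_50pct),
                   incorrect_response = sum(v$incorrect_response)))
}
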