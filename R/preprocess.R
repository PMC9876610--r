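# Raw gaze samples -> AOI-labelled fixations -> trial validity.
# Order of operations follows the standard pipeline for this task:
# per-eye gap interpolation, binocular averaging, dispersion-based
# fixation detection, AOI assignment, exclusion rules.

# Fill maximal invalid runs bounded by valid samples on both sides whose
# bounding-sample time gap is <= max_gap, by linear interpolation of each
# coordinate. Edge runs and longer runs are left untouched.
fill_gaps_1d <- function(t, x, y, valid, max_gap) {
  if (is.unsorted(t, strictly = TRUE)) stop("timestamps must be strictly increasing")
  if (all(valid) || !any(valid)) {
    return(list(x = x, y = y, valid = valid))
  }
  r <- rle(valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (r$values[k]) next
    if (k == 1L || k == length(r$values)) next  # edge run: no bounding samples
    i0 <- starts[k] - 1L      # last valid before
    i1 <- ends[k] + 1L        # first valid after
    if (t[i1] - t[i0] > max_gap) next
    idx <- starts[k]:ends[k]
    f <- (t[idx] - t[i0]) / (t[i1] - t[i0])
    x[idx] <- x[i0] + f * (x[i1] - x[i0])
    y[idx] <- y[i0] + f * (y[i1] - y[i0])
    valid[idx] <- TRUE
  }
  list(x = x, y = y, valid = valid)
}

#' Interpolate short tracking gaps
#'
#' Fills runs of invalid samples by linear interpolation, separately per
#' eye, when the run is bounded by valid samples on both sides and the
#' time gap between those bounding samples does not exceed `max_gap`
#' (default 75 ms). Longer runs, and runs touching the start or end of the
#' trial, are left invalid. Valid samples are never altered.
#'
#' @param samples data.frame/data.table with `t_ms`, `lx_px`, `ly_px`,
#'   `l_valid`, `rx_px`, `ry_px`, `r_valid` (a cyclopean table with
#'   `x_px`, `y_px`, `valid` is also accepted).
#' @param max_gap maximum bridgeable gap in ms.
#' @return table of the same shape with gaps filled.
#' @export
interpolate_gaps <- function(samples, max_gap = 75) {
  s <- data.table::as.data.table(samples)
  if (all(c("x_px", "y_px", "valid") %in% names(s))) {
    g <- fill_gaps_1d(s$t_ms, s$x_px, s$y_px, s$valid, max_gap)
    s[, `:=`(x_px = g$x, y_px = g$y, valid = g$valid)]
    return(s[])
  }
  gl <- fill_gaps_1d(s$t_ms, s$lx_px, s$ly_px, s$l_valid, max_gap)
  gr <- fill_gaps_1d(s$t_ms, s$rx_px, s$ry_px, s$r_valid, max_gap)
  s[, `:=`(lx_px = gl$x, ly_px = gl$y, l_valid = gl$valid,
           rx_px = gr$x, ry_px = gr$y, r_valid = gr$valid)]
  s[]
}

#' Average the two eyes into a cyclopean gaze stream
#'
#' Per sample: both eyes valid gives the coordinate mean; exactly one
#' valid eye is used as-is (maximizing data retention); neither valid
#' yields an invalid sample.
#'
#' @param samples binocular sample table (see [interpolate_gaps()]).
#' @return data.table with `t_ms`, `x_px`, `y_px`, `valid`.
#' @export
merge_binocular <- function(samples) {
  s <- data.table::as.data.table(samples)
  lv <- s$l_valid; rv <- s$r_valid
  x <- ifelse(lv & rv, (s$lx_px + s$rx_px) / 2, ifelse(lv, s$lx_px, s$rx_px))
  y <- ifelse(lv & rv, (s$ly_px + s$ry_px) / 2, ifelse(lv, s$ly_px, s$ry_px))
  valid <- lv | rv
  x[!valid] <- NA_real_
  y[!valid] <- NA_real_
  data.table::data.table(t_ms = s$t_ms, x_px = x, y_px = y, valid = valid)
}

# Greedy maximal-window I-DT over one fully-valid segment.
# Dispersion = (max x - min x) + (max y - min y); a fixation is a maximal
# window with dispersion <= threshold, kept if its duration (exclusive
# offset: last sample time + one period - onset) >= min duration.
idt_segment <- function(t, x, y, dispersion, min_dur, period) {
  n <- length(t)
  out <- list()
  i <- 1L
  while (i <= n) {
    xmin <- x[i]; xmax <- x[i]; ymin <- y[i]; ymax <- y[i]
    j <- i
    while (j < n) {
      nx <- x[j + 1L]; ny <- y[j + 1L]
      nxmin <- if (nx < xmin) nx else xmin
      nxmax <- if (nx > xmax) nx else xmax
      nymin <- if (ny < ymin) ny else ymin
      nymax <- if (ny > ymax) ny else ymax
      if ((nxmax - nxmin) + (nymax - nymin) > dispersion) break
      xmin <- nxmin; xmax <- nxmax; ymin <- nymin; ymax <- nymax
      j <- j + 1L
    }
    dur <- t[j] + period - t[i]
    if (dur >= min_dur) {
      out[[length(out) + 1L]] <- c(onset = t[i], offset = t[j] + period,
                                   cx = mean(x[i:j]), cy = mean(y[i:j]))
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  out
}

# Velocity-threshold (I-VT) variant: samples slower than vel_thresh
# (px/ms) group into candidate fixations; runs shorter than min_dur drop.
ivt_segment <- function(t, x, y, vel_thresh, min_dur, period) {
  n <- length(t)
  if (n < 2) return(list())
  v <- c(0, sqrt(diff(x)^2 + diff(y)^2) / diff(t))
  slow <- v <= vel_thresh
  r <- rle(slow)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    i <- starts[k]; j <- ends[k]
    dur <- t[j] + period - t[i]
    if (dur >= min_dur) {
      out[[length(out) + 1L]] <- c(onset = t[i], offset = t[j] + period,
                                   cx = mean(x[i:j]), cy = mean(y[i:j]))
    }
  }
  out
}

#' Detect fixations in a cyclopean gaze stream
#'
#' Default algorithm is dispersion-based (I-DT): fixations are maximal
#' sample windows whose dispersion (x range + y range) stays within
#' `dispersion_px` and whose duration reaches `min_duration_ms`; the
#' centroid is the mean of member samples. Invalid samples break windows.
#' A velocity-threshold variant (I-VT) is available via `method = "ivt"`.
#'
#' @param samples cyclopean table from [merge_binocular()] (columns
#'   `t_ms`, `x_px`, `y_px`, `valid`).
#' @param dispersion_px I-DT dispersion threshold in pixels
#'   (default one degree of visual angle).
#' @param min_duration_ms minimum fixation duration.
#' @param method `"idt"` or `"ivt"`.
#' @param velocity_px_ms I-VT velocity threshold (px/ms); default
#'   corresponds to 30 deg/s.
#' @return data.frame with `onset_ms`, `offset_ms` (exclusive),
#'   `duration_ms`, `cx`, `cy`.
#' @export
detect_fixations <- function(samples, dispersion_px = px_per_degree(),
                             min_duration_ms = 60,
                             method = c("idt", "ivt"),
                             velocity_px_ms = 30 * px_per_degree() / 1000) {
  method <- match.arg(method)
  s <- data.table::as.data.table(samples)
  n <- nrow(s)
  if (n == 0) {
    return(data.frame(onset_ms = numeric(0), offset_ms = numeric(0),
                      duration_ms = numeric(0), cx = numeric(0),
                      cy = numeric(0)))
  }
  period <- if (n > 1) stats::median(diff(s$t_ms)) else 1
  r <- rle(s$valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  fixes <- list()
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    idx <- starts[k]:ends[k]
    seg <- if (method == "idt") {
      idt_segment(s$t_ms[idx], s$x_px[idx], s$y_px[idx],
                  dispersion_px, min_duration_ms, period)
    } else {
      ivt_segment(s$t_ms[idx], s$x_px[idx], s$y_px[idx],
                  velocity_px_ms, min_duration_ms, period)
    }
    fixes <- c(fixes, seg)
  }
  if (length(fixes) == 0) {
    return(data.frame(onset_ms = numeric(0), offset_ms = numeric(0),
                      duration_ms = numeric(0), cx = numeric(0),
                      cy = numeric(0)))
  }
  m <- do.call(rbind, fixes)
  data.frame(onset_ms = m[, "onset"], offset_ms = m[, "offset"],
             duration_ms = m[, "offset"] - m[, "onset"],
             cx = m[, "cx"], cy = m[, "cy"])
}

#' Label fixations by area of interest
#'
#' Centroid inside the eyes rectangle gives `eyes`; else inside the face
#' rectangle gives `face`; else `off`. Rectangle membership is half-open
#' (a centroid exactly on the right/bottom edge falls outside).
#'
#' @param fixations fixation table from [detect_fixations()].
#' @param aois an [aoi_set()].
#' @return the fixation table with an `aoi` column appended.
#' @export
assign_aoi <- function(fixations, aois = default_aois()) {
  stopifnot(inherits(aois, "aoi_set"))
  aoi <- ifelse(in_rect(fixations$cx, fixations$cy, aois$eyes), "eyes",
                ifelse(in_rect(fixations$cx, fixations$cy, aois$face),
                       "face", "off"))
  fixations$aoi <- aoi
  fixations
}

#' Classify a trial as valid or invalid
#'
#' Applies the exclusion rules: more than `missing_max` (default 30%)
#' missing gaze data after interpolation excludes the trial; less than
#' `face_min` (default 50%) of the trial spent looking at the face
#' (eyes + rest of face) excludes it; an incorrect behavioural response
#' excludes it. Thresholds are strict inequalities, so a trial at exactly
#' 30% missing and exactly 50% face time is valid.
#'
#' @param samples post-interpolation cyclopean samples for the trial.
#' @param fixations AOI-labelled fixations for the trial.
#' @param correct logical: was the behavioural response correct?
#' @param missing_max,face_min exclusion thresholds (fractions).
#' @param duration_ms trial duration.
#' @param face_time_from `"fixations"` (default) computes face time from
#'   fixation durations; `"samples"` counts raw samples inside the AOIs.
#' @param aois AOI set, needed only for `face_time_from = "samples"`.
#' @return one-row data.frame: `valid`, `missing_fraction`,
#'   `face_fraction`, and logical reason columns `missing_gt_30pct`,
#'   `face_lt_50pct`, `incorrect_response`.
#' @export
validate_trial <- function(samples, fixations, correct,
                           missing_max = 0.30, face_min = 0.50,
                           duration_ms = 10000,
                           face_time_from = c("fixations", "samples"),
                           aois = default_aois()) {
  face_time_from <- match.arg(face_time_from)
  if (is.na(correct)) stop("trial has no response record in the manifest")
  missing_fraction <- 1 - sum(samples$valid) * (duration_ms / nrow(samples)) /
    duration_ms
  face_fraction <- if (face_time_from == "fixations") {
    sum(fixations$duration_ms[fixations$aoi %in% c("eyes", "face")]) /
      duration_ms
  } else {
    mean(in_rect(samples$x_px, samples$y_px, aois$face))
  }
  r_missing <- missing_fraction > missing_max
  r_face <- face_fraction < face_min
  r_incorrect <- !correct
  data.frame(valid = !(r_missing || r_face || r_incorrect),
             missing_fraction = missing_fraction,
             face_fraction = face_fraction,
             missing_gt_30pct = r_missing,
             face_lt_50pct = r_face,
             incorrect_response = r_incorrect)
}

#' Preprocess one trial
#'
#' Runs gap interpolation, binocular averaging, fixation detection, AOI
#' assignment and validity classification for a single trial.
#'
#' @param samples raw binocular samples for one trial.
#' @param correct logical response flag from the manifest.
#' @param config pipeline configuration, see [default_config()].
#' @param aois AOI set.
#' @return list with `fixations` (AOI-labelled) and `validity` (one row).
#' @export
preprocess_trial <- function(samples, correct, config = default_config(),
                             aois = default_aois()) {
  s <- interpolate_gaps(samples, max_gap = config$interpolation$max_gap_ms)
  cyc <- merge_binocular(s)
  fx <- detect_fixations(cyc,
                         dispersion_px = config$fixation$dispersion_px,
                         min_duration_ms = config$fixation$min_duration_ms,
                         method = config$fixation$method)
  fx <- assign_aoi(fx, aois)
  val <- validate_trial(cyc, fx, correct,
                        missing_max = config$validity$missing_max,
                        face_min = config$validity$face_min,
                        duration_ms = config$trial$duration_ms,
                        face_time_from = config$validity$face_time_from,
                        aois = aois)
  list(fixations = fx, validity = val)
}

#' Preprocess a full dataset
#'
#' Applies [preprocess_trial()] to every trial in a long-format gaze table,
#' joining response correctness from the trial manifest.
#'
#' @param gaze long gaze table (`participant_id, block, trial, t_ms, ...`).
#' @param manifest trial manifest with `participant_id, block, trial, correct`.
#' @param config pipeline configuration.
#' @param aois AOI set.
#' @return list with `fixations` (one table, trial identifiers included)
#'   and `validity` (one row per trial).
#' @export
preprocess_dataset <- function(gaze, manifest, config = default_config(),
                               aois = default_aois()) {
  g <- data.table::as.data.table(gaze)
  man <- data.table::as.data.table(manifest)
  keys <- c("participant_id", "block", "trial")
  chunks <- split(g, by = keys, sorted = TRUE)
  man_key <- paste(man$participant_id, man$block, man$trial, sep = ".")
  fix_out <- vector("list", length(chunks))
  val_out <- vector("list", length(chunks))
  for (i in seq_along(chunks)) {
    s <- chunks[[i]]
    id <- s[1, keys, with = FALSE]
    mi <- match(names(chunks)[i], man_key)
    if (is.na(mi) || is.na(man$correct[mi])) {
      stop("manifest entry missing for trial ", names(chunks)[i])
    }
    res <- preprocess_trial(s, man$correct[mi], config, aois)
    if (nrow(res$fixations) > 0) {
      fix_out[[i]] <- cbind(id, res$fixations, row.names = NULL)
    }
    val_out[[i]] <- cbind(id, res$validity, row.names = NULL)
  }
  list(fixations = data.table::rbindlist(fix_out),
       validity = data.table::rbindlist(val_out))
}
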