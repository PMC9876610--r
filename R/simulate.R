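# Forward model for free-viewing gaze data: a cohort with correlated
# autistic-trait (AQ) and social-anxiety (SPIN) scores, and per-trial
# 300 Hz gaze streams generated from an AOI-level semi-Markov fixation
# schedule whose parameters the traits modulate. Every generative choice
# is recorded as ground truth so downstream recovery can be tested.

#' Simulation parameters
#'
#' Returns the full parameter set of the synthetic-data generator with
#' defaults that emulate the study conditions this pipeline is built for:
#' a 60-participant cohort, 4 blocks x 20 trials of 10-s face viewing
#' sampled at 300 Hz on a 1920 x 1080 screen, AQ (4-point) and SPIN totals
#' correlated at r = 0.44, trait-dependent first-fixation behaviour and a
#' late-window eye-looking decrement growing with autistic traits.
#'
#' Trait effects enter linearly on the log-latency, log-duration and
#' logit-probability scales, with an AQ x SPIN product term, mirroring the
#' moderation models fitted downstream. Latency and first-fixation duration
#' are log-normal; subsequent AOI dwell times are gamma. `z_aq4` / `z_spin`
#' inside the generator are standardized against the population moments
#' (`aq4_mean`/`aq4_sd` etc.), not the realized sample.
#'
#' @param n_participants cohort size.
#' @param n_blocks,trials_per_block trial design (trials_per_block must be
#'   divisible by the number of emotions so blocks are balanced).
#' @param duration_ms,sample_rate stimulus duration (ms) and tracker rate (Hz).
#' @param screen screen size in pixels.
#' @param aois AOI geometry used to place simulated fixations, see [aoi_set()].
#' @param trait_corr target Pearson correlation of aq4 and spin.
#' @param aq4_mean,aq4_sd,spin_mean,spin_sd trait population moments.
#' @param age_mean,age_sd,prop_female demographics.
#' @param latency_base,latency_sd log-scale mean/sd of the latency (ms) from
#'   face onset to the first on-face fixation.
#' @param latency_b_aq,latency_b_spin,latency_b_int trait slopes on
#'   log-latency (per population SD; `_int` multiplies z_aq * z_spin).
#' @param first_eye_logit baseline logit that the first on-face fixation
#'   lands on the eyes.
#' @param first_eye_b_aq,first_eye_b_spin,first_eye_b_int trait slopes on
#'   that logit.
#' @param dur_base,dur_sd,dur_ranef_sd log-scale mean/sd of the first
#'   eyes-fixation duration (ms) and the SD of its participant-level
#'   random intercept.
#' @param dur_b_aq,dur_b_spin,dur_b_int trait slopes on log-duration.
#' @param eyes_logit,eyes_ranef_sd baseline logit that a post-initial
#'   fixation transitions to the eyes, and its participant random-intercept SD.
#' @param eyes_b_aq,eyes_b_spin,eyes_b_int trait slopes on that logit.
#' @param p_off probability weight of leaving the face at a transition.
#' @param dwell_shape,dwell_mean_eyes,dwell_mean_face,dwell_mean_off gamma
#'   dwell-time parameters (shape; means in ms) per AOI.
#' @param avoidance_effect late-window decrement of the eyes-transition
#'   logit per population SD of AQ (positive = high-AQ simulants look at
#'   the eyes less after `avoidance_onset_ms`).
#' @param avoidance_onset_ms onset of the late window.
#' @param emotion_offsets named additive offsets (logit scale) on the
#'   eyes-transition probability per emotion; default zero.
#' @param fix_noise_sd within-fixation coordinate noise SD (px) of the
#'   cyclopean path.
#' @param eye_offset_sd independent per-eye noise SD (px) around the
#'   cyclopean path.
#' @param missing_burst_rate rate (bursts per second) of tracking-loss bursts.
#' @param missing_burst_mean_ms mean burst duration (exponential).
#' @param bad_trial_rate probability a trial suffers degraded tracking,
#'   multiplying the burst rate and mean duration by
#'   `bad_trial_missing_mult` / `bad_trial_dur_mult`; such trials usually
#'   cross the 30%-missing exclusion threshold, emulating the realistic
#'   missing-data bursts of desktop eye-tracking sessions.
#' @param bad_trial_missing_mult,bad_trial_dur_mult degradation multipliers.
#' @param accuracy probability a trial's emotion judgment is correct.
#' @param seed global integer seed; all draws derive from it.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(n_participants = 60,
                       n_blocks = 4, trials_per_block = 20,
                       duration_ms = 10000, sample_rate = 300,
                       screen = c(1920, 1080),
                       aois = default_aois(screen = screen),
                       trait_corr = 0.44,
                       aq4_mean = 120.35, aq4_sd = 14.28,
                       spin_mean = 24.37, spin_sd = 12.47,
                       age_mean = 22.02, age_sd = 2.45,
                       prop_female = 39 / 60,
                       latency_base = log(350), latency_sd = 0.35,
                       latency_b_aq = 0, latency_b_spin = 0,
                       latency_b_int = 0.08,
                       first_eye_logit = 0,
                       first_eye_b_aq = 0, first_eye_b_spin = 0,
                       first_eye_b_int = -0.35,
                       dur_base = log(350), dur_sd = 0.45,
                       dur_ranef_sd = 0.15,
                       dur_b_aq = 0, dur_b_spin = 0.125, dur_b_int = 0.125,
                       eyes_logit = -0.35, eyes_ranef_sd = 0.5,
                       eyes_b_aq = 0, eyes_b_spin = 0, eyes_b_int = 0,
                       p_off = 0.06,
                       dwell_shape = 4, dwell_mean_eyes = 420,
                       dwell_mean_face = 520, dwell_mean_off = 280,
                       avoidance_effect = 1.5, avoidance_onset_ms = 5000,
                       emotion_offsets = c(angry = 0, fearful = 0, happy = 0,
                                           sad = 0, neutral = 0),
                       fix_noise_sd = 2.5, eye_offset_sd = 2,
                       missing_burst_rate = 0.25,
                       missing_burst_mean_ms = 60,
                       bad_trial_rate = 0.07,
                       bad_trial_missing_mult = 25,
                       bad_trial_dur_mult = 3,
                       accuracy = 0.885,
                       seed = 1L) {
  p <- as.list(environment())
  validate_sim_params(p)
  class(p) <- "sim_params"
  p
}

validate_sim_params <- function(p) {
  if (p$n_participants < 2) stop("n_participants must be at least 2")
  if (abs(p$trait_corr) >= 1) stop("trait_corr must lie strictly in (-1, 1)")
  n_samp <- p$duration_ms * p$sample_rate / 1000
  if (abs(n_samp - round(n_samp)) > 1e-9) {
    stop("sample_rate x duration must yield an integer sample count")
  }
  if (p$accuracy < 0 || p$accuracy > 1 || p$p_off < 0 || p$p_off > 1 ||
      p$prop_female < 0 || p$prop_female > 1) {
    stop("probabilities must lie in [0, 1]")
  }
  if (p$bad_trial_rate < 0 || p$bad_trial_rate > 1) {
    stop("probabilities must lie in [0, 1]")
  }
  if (p$missing_burst_rate < 0 || p$missing_burst_mean_ms < 0 ||
      any(c(p$dwell_mean_eyes, p$dwell_mean_face, p$dwell_mean_off,
            p$dwell_shape, p$latency_sd, p$dur_sd, p$fix_noise_sd,
            p$eye_offset_sd) < 0)) {
    stop("rates, durations and SDs must be non-negative")
  }
  emos <- c("angry", "fearful", "happy", "sad", "neutral")
  if (!all(emos %in% names(p$emotion_offsets))) {
    stop("emotion_offsets must name all five emotions")
  }
  if (p$trials_per_block %% length(emos) != 0) {
    stop("trials_per_block must be divisible by the number of emotions")
  }
  invisible(p)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Gaze simulation parameters:",
      sprintf("%d participants, %d x %d trials, %g s @ %g Hz, seed %d\n",
              x$n_participants, x$n_blocks, x$trials_per_block,
              x$duration_ms / 1000, x$sample_rate, x$seed))
  invisible(x)
}

sim_emotions <- function() c("angry", "fearful", "happy", "sad", "neutral")

# Deterministic per-unit seed derived from the global seed so that any
# participant/trial can be regenerated independently of generation order.
derive_seed <- function(seed, i, j = 0L) {
  m <- 2147483563
  s <- (as.numeric(seed) %% m) * 40014 + i * 7919 + j * 104729
  as.integer(s %% m + 1)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate a simulated cohort
#'
#' Draws `n` participants with (aq4, spin) from a bivariate normal with the
#' target correlation, rounded and clipped to the scales' ranges (AQ 4-point
#' 50-200, SPIN 0-68). The dichotomous AQ total is derived from the 4-point
#' total by the calibrated monotone map `round((aq4 - 50) / 3)` clipped to
#' 0-50, which maps the scale endpoints onto each other and reproduces the
#' observed pairing of means (4-point ~120 with dichotomous ~23). Latent
#' participant random effects used by the trial generator are returned in
#' `ranef_eyes` / `ranef_dur`; `z_aq4_true` / `z_spin_true` are the
#' population-standardized traits the generative effects act on.
#'
#' @param n cohort size (>= 2).
#' @param params a [sim_params()] object.
#' @param seed optional seed override (defaults to the seed in `params`).
#' @return data.frame, one row per participant.
#' @export
gen_cohort <- function(n = params$n_participants, params = sim_params(),
                       seed = params$seed) {
  if (n < 2) stop("n must be at least 2")
  if (abs(params$trait_corr) >= 1) stop("trait_corr must lie strictly in (-1, 1)")
  set.seed(derive_seed(seed, 0L))
  r <- params$trait_corr
  z1 <- stats::rnorm(n)
  z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(n)
  aq4_raw <- params$aq4_mean + params$aq4_sd * z1
  spin_raw <- params$spin_mean + params$spin_sd * z2
  aq4 <- as.integer(clip(round(aq4_raw), 50, 200))
  spin <- as.integer(clip(round(spin_raw), 0, 68))
  aq_binary <- as.integer(clip(round((aq4 - 50) / 3), 0, 50))
  data.frame(
    participant_id = sprintf("P%03d", seq_len(n)),
    age = round(clip(stats::rnorm(n, params$age_mean, params$age_sd), 18, 40), 1),
    sex = ifelse(stats::runif(n) < params$prop_female, "female", "male"),
    aq4 = aq4,
    aq_binary = aq_binary,
    spin = spin,
    z_aq4_true = (aq4_raw - params$aq4_mean) / params$aq4_sd,
    z_spin_true = (spin_raw - params$spin_mean) / params$spin_sd,
    ranef_eyes = stats::rnorm(n, 0, params$eyes_ranef_sd),
    ranef_dur = stats::rnorm(n, 0, params$dur_ranef_sd),
    stringsAsFactors = FALSE
  )
}

#' Generate one trial's ground-truth AOI schedule
#'
#' Produces the semi-Markov fixation schedule for a single 10-s trial:
#' an initial latency period with gaze parked at the peripheral fixation
#' location (off-face), then a first on-face fixation landing on the eyes
#' with trait-modulated probability, then alternating fixations on
#' \{eyes, face, off\} with trait-modulated transition probabilities and
#' gamma dwell times. All segment durations are quantized to whole sample
#' periods and sum exactly to the trial length. Saccades are instantaneous:
#' the gaze point jumps between successive fixation targets.
#'
#' @param participant one row of [gen_cohort()] output.
#' @param emotion one of the five emotion labels.
#' @param fixation_side `"left"` or `"right"` peripheral fixation.
#' @param params a [sim_params()] object.
#' @param seed integer seed for this trial.
#' @return data.frame with one row per fixation segment: `aoi`,
#'   `start_sample` (0-based), `n_samples`, `cx`, `cy`.
#' @export
gen_trial_schedule <- function(participant, emotion, fixation_side,
                               params, seed) {
  set.seed(seed)
  period <- 1000 / params$sample_rate
  n_total <- as.integer(round(params$duration_ms / period))
  min_seg <- max(2L, as.integer(ceiling(80 / period)))  # >= 80 ms per segment
  zaq <- participant$z_aq4_true
  zsp <- participant$z_spin_true
  emo_off <- params$emotion_offsets[[emotion]]

  # precomputed sampling bounds per AOI (30 px margin inside rectangles)
  a <- params$aois
  eb <- c(a$eyes["x0"] + 30, a$eyes["x1"] - 30,
          a$eyes["y0"] + 30, a$eyes["y1"] - 30)
  fb <- c(a$face["x0"] + 30, a$face["x1"] - 30,
          a$eyes["y1"] + 10, a$face["y1"] - 30)
  h <- a$screen[2]
  ob <- if (fixation_side == "left") {
    c(60, a$face["x0"] - 80, 0.3 * h, 0.7 * h)
  } else {
    c(a$face["x1"] + 80, a$screen[1] - 60, 0.3 * h, 0.7 * h)
  }
  draw_point <- function(aoi) {
    b <- if (aoi == "eyes") eb else if (aoi == "face") fb else ob
    c(stats::runif(1, b[1], max(b[2], b[1] + 1)),
      stats::runif(1, b[3], max(b[4], b[3] + 1)))
  }

  cap <- 64L
  segs_aoi <- character(cap); segs_n <- integer(cap)
  segs_x <- numeric(cap); segs_y <- numeric(cap)
  k <- 0L
  push <- function(aoi, n, pt) {
    k <<- k + 1L
    if (k > length(segs_n)) {  # grow geometrically, rarely hit
      segs_aoi <<- c(segs_aoi, character(k)); segs_n <<- c(segs_n, integer(k))
      segs_x <<- c(segs_x, numeric(k)); segs_y <<- c(segs_y, numeric(k))
    }
    segs_aoi[k] <<- aoi; segs_n[k] <<- n
    segs_x[k] <<- pt[1]; segs_y[k] <<- pt[2]
  }

  # initial latency: gaze holds near the (extinguished) peripheral fixation
  lat_mu <- params$latency_base + params$latency_b_aq * zaq +
    params$latency_b_spin * zsp + params$latency_b_int * zaq * zsp
  lat_ms <- exp(stats::rnorm(1, lat_mu, params$latency_sd))
  lat_n <- clip(as.integer(round(lat_ms / period)), min_seg, n_total - 2L * min_seg)
  push("off", lat_n, draw_point("off"))

  # first on-face fixation
  p_eye1 <- stats::plogis(params$first_eye_logit +
                          params$first_eye_b_aq * zaq +
                          params$first_eye_b_spin * zsp +
                          params$first_eye_b_int * zaq * zsp + emo_off)
  used <- lat_n
  if (stats::runif(1) < p_eye1) {
    dur_mu <- params$dur_base + participant$ranef_dur +
      params$dur_b_aq * zaq + params$dur_b_spin * zsp +
      params$dur_b_int * zaq * zsp
    d_ms <- exp(stats::rnorm(1, dur_mu, params$dur_sd))
    first_aoi <- "eyes"
  } else {
    d_ms <- stats::rgamma(1, shape = params$dwell_shape,
                          scale = params$dwell_mean_face / params$dwell_shape)
    first_aoi <- "face"
  }
  d_n <- clip(as.integer(round(d_ms / period)), min_seg, n_total - used - min_seg)
  push(first_aoi, d_n, draw_point(first_aoi))
  used <- used + d_n

  # subsequent fixations: semi-Markov without self-transitions
  cur <- first_aoi
  base_logit <- params$eyes_logit + participant$ranef_eyes +
    params$eyes_b_aq * zaq + params$eyes_b_spin * zsp +
    params$eyes_b_int * zaq * zsp + emo_off
  pe_early <- stats::plogis(base_logit)
  pe_late <- stats::plogis(base_logit - params$avoidance_effect * zaq)
  p_off <- params$p_off
  shape <- params$dwell_shape
  scale_eyes <- params$dwell_mean_eyes / shape
  scale_face <- params$dwell_mean_face / shape
  scale_off <- params$dwell_mean_off / shape
  onset_late <- params$avoidance_onset_ms
  while (used < n_total) {
    pe <- if (used * period >= onset_late) pe_late else pe_early
    w_eyes <- pe; w_face <- (1 - pe) * (1 - p_off); w_off <- (1 - pe) * p_off
    if (cur == "eyes") w_eyes <- 0
    else if (cur == "face") w_face <- 0
    else w_off <- 0
    tot <- w_eyes + w_face + w_off
    if (tot == 0) {  # degenerate pe/p_off combination
      if (cur == "eyes") w_face <- w_off <- 1
      else if (cur == "face") w_eyes <- w_off <- 1
      else w_eyes <- w_face <- 1
      tot <- 2
    }
    u <- stats::runif(1) * tot
    nxt <- if (u < w_eyes) "eyes" else if (u < w_eyes + w_face) "face" else "off"
    scl <- if (nxt == "eyes") scale_eyes else if (nxt == "face") scale_face
           else scale_off
    d_n <- max(as.integer(round(stats::rgamma(1, shape = shape,
                                              scale = scl) / period)), min_seg)
    if (used + d_n > n_total - min_seg) d_n <- n_total - used  # absorb tail
    push(nxt, d_n, draw_point(nxt))
    used <- used + d_n
    cur <- nxt
  }
  idx <- seq_len(k)
  n_v <- segs_n[idx]
  structure(list(aoi = segs_aoi[idx],
                 start_sample = cumsum(c(0L, n_v[-k])),
                 n_samples = n_v, cx = segs_x[idx], cy = segs_y[idx]),
            class = "data.frame", row.names = c(NA_integer_, -k))
}

#' Rasterize a schedule into 300 Hz gaze samples
#'
#' Expands an AOI schedule into per-sample binocular gaze data: the
#' cyclopean path is the segment target plus iid coordinate noise, each
#' eye is the cyclopean point plus small independent noise, and tracking
#' losses are Poisson bursts of invalid samples (both eyes, coordinates NA).
#'
#' @param schedule output of [gen_trial_schedule()].
#' @param params a [sim_params()] object.
#' @param seed integer seed for the noise and missingness draws.
#' @return data.table: `t_ms, lx_px, ly_px, l_valid, rx_px, ry_px, r_valid`.
#' @export
rasterize_schedule <- function(schedule, params, seed) {
  set.seed(seed)
  period <- 1000 / params$sample_rate
  n <- sum(schedule$n_samples)
  cx <- rep(schedule$cx, schedule$n_samples)
  cy <- rep(schedule$cy, schedule$n_samples)
  if (params$fix_noise_sd > 0) {
    cx <- cx + stats::rnorm(n, 0, params$fix_noise_sd)
    cy <- cy + stats::rnorm(n, 0, params$fix_noise_sd)
  }
  noise <- function() if (params$eye_offset_sd > 0)
    stats::rnorm(n, 0, params$eye_offset_sd) else numeric(n)
  lx <- cx + noise(); ly <- cy + noise()
  rx <- cx + noise(); ry <- cy + noise()
  valid <- rep(TRUE, n)
  if (params$missing_burst_rate > 0) {
    bad <- stats::runif(1) < params$bad_trial_rate
    rate <- params$missing_burst_rate *
      if (bad) params$bad_trial_missing_mult else 1
    mean_ms <- params$missing_burst_mean_ms *
      if (bad) params$bad_trial_dur_mult else 1
    k <- stats::rpois(1, rate * params$duration_ms / 1000)
    if (k > 0) {
      starts <- stats::runif(k, 0, params$duration_ms)
      durs <- stats::rexp(k, 1 / mean_ms)
      for (b in seq_len(k)) {
        i0 <- as.integer(floor(starts[b] / period)) + 1L
        i1 <- min(as.integer(ceiling((starts[b] + durs[b]) / period)), n)
        if (i0 <= i1) valid[i0:i1] <- FALSE
      }
    }
  }
  lx[!valid] <- NA_real_; ly[!valid] <- NA_real_
  rx[!valid] <- NA_real_; ry[!valid] <- NA_real_
  data.table::data.table(
    t_ms = (seq_len(n) - 1) * period,
    lx_px = lx, ly_px = ly, l_valid = valid,
    rx_px = rx, ry_px = ry, r_valid = valid
  )
}

#' Generate one trial (schedule + samples)
#'
#' @inheritParams gen_trial_schedule
#' @return list with `schedule` and `samples`.
#' @export
gen_trial_gaze <- function(participant, emotion, fixation_side, params, seed) {
  schedule <- gen_trial_schedule(participant, emotion, fixation_side,
                                 params, seed)
  samples <- rasterize_schedule(schedule, params, derive_seed(seed, 1L))
  list(schedule = schedule, samples = samples)
}

#' Ground-truth schedule as a fixation table
#'
#' Converts an AOI schedule into the same layout the fixation detector
#' emits (`onset_ms, offset_ms, duration_ms, cx, cy, aoi`), so the metric
#' functions can run directly on ground truth. Offsets are exclusive:
#' a segment of k samples spans k sample periods.
#'
#' @param schedule output of [gen_trial_schedule()].
#' @param sample_rate tracker rate in Hz.
#' @return data.frame of fixation rows.
#' @export
schedule_fixations <- function(schedule, sample_rate = 300) {
  period <- 1000 / sample_rate
  data.frame(
    onset_ms = schedule$start_sample * period,
    offset_ms = (schedule$start_sample + schedule$n_samples) * period,
    duration_ms = schedule$n_samples * period,
    cx = schedule$cx, cy = schedule$cy,
    aoi = schedule$aoi,
    stringsAsFactors = FALSE
  )
}

#' Generate a full synthetic dataset
#'
#' Draws a cohort, a balanced trial design (each block presents every
#' emotion equally often in shuffled order, peripheral fixation side at
#' random), per-trial AOI schedules, and (optionally) rasterized 300 Hz
#' gaze samples. Response correctness is Bernoulli with the configured
#' accuracy. If `dir` is given, writes the on-disk dataset: `gaze.tsv`
#' (long format), `manifest.csv`, `participants.csv` and
#' `ground_truth.json` (all generative parameters plus the per-trial AOI
#' interval list).
#'
#' @param params a [sim_params()] object.
#' @param dir optional output directory.
#' @param rasterize if FALSE, skip 300 Hz rasterization (schedules only);
#'   `gaze` is then NULL and metrics can be computed from
#'   [schedule_fixations()].
#' @return (invisibly) list with `participants`, `manifest`, `gaze`
#'   (data.table or NULL), `schedules` (list keyed participant/block/trial),
#'   and `params`.
#' @export
gen_dataset <- function(params = sim_params(), dir = NULL, rasterize = TRUE) {
  validate_sim_params(params)
  cohort <- gen_cohort(params$n_participants, params, seed = params$seed)
  emos <- sim_emotions()
  n_trials <- params$n_blocks * params$trials_per_block

  manifest <- vector("list", params$n_participants)
  schedules <- vector("list", params$n_participants * n_trials)
  gaze <- if (rasterize) vector("list", params$n_participants * n_trials) else NULL
  k <- 0L
  for (i in seq_len(params$n_participants)) {
    prt <- cohort[i, ]
    set.seed(derive_seed(params$seed, i, 0L))
    emo_order <- unlist(lapply(seq_len(params$n_blocks), function(b)
      sample(rep(emos, params$trials_per_block / length(emos)))))
    man_i <- data.frame(
      participant_id = prt$participant_id,
      block = rep(seq_len(params$n_blocks), each = params$trials_per_block),
      trial = rep(seq_len(params$trials_per_block), params$n_blocks),
      emotion = emo_order,
      fixation_side = sample(c("left", "right"), n_trials, replace = TRUE),
      correct = stats::runif(n_trials) < params$accuracy,
      stringsAsFactors = FALSE
    )
    man_i$response <- ifelse(man_i$correct, man_i$emotion, "other")
    manifest[[i]] <- man_i
    for (j in seq_len(n_trials)) {
      k <- k + 1L
      tseed <- derive_seed(params$seed, i, j)
      sch <- gen_trial_schedule(prt, man_i$emotion[j], man_i$fixation_side[j],
                                params, tseed)
      schedules[[k]] <- sch
      if (rasterize) {
        g <- rasterize_schedule(sch, params, derive_seed(tseed, 1L))
        g[, `:=`(participant_id = prt$participant_id,
                 block = man_i$block[j], trial = man_i$trial[j])]
        gaze[[k]] <- g
      }
    }
  }
  manifest <- do.call(rbind, manifest)
  names(schedules) <- paste(manifest$participant_id, manifest$block,
                            manifest$trial, sep = "_")
  if (rasterize) {
    gaze <- data.table::rbindlist(gaze)
    data.table::setcolorder(gaze, c("participant_id", "block", "trial", "t_ms",
                                    "lx_px", "ly_px", "l_valid",
                                    "rx_px", "ry_px", "r_valid"))
  }
  out <- list(participants = cohort, manifest = manifest, gaze = gaze,
              schedules = schedules, params = params)
  if (!is.null(dir)) write_dataset(out, dir)
  invisible(out)
}

#' Write a generated dataset to disk
#'
#' @param dataset output of [gen_dataset()].
#' @param dir output directory (created if needed).
#' @return (invisibly) the directory.
#' @export
write_dataset <- function(dataset, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok) stop("cannot create output directory: ", dir)
  pub <- dataset$participants[, c("participant_id", "age", "sex",
                                  "aq4", "aq_binary", "spin")]
  utils::write.csv(pub, file.path(dir, "participants.csv"), row.names = FALSE)
  utils::write.csv(dataset$manifest[, c("participant_id", "block", "trial",
                                        "emotion", "fixation_side",
                                        "response", "correct")],
                   file.path(dir, "manifest.csv"), row.names = FALSE)
  if (!is.null(dataset$gaze)) {
    data.table::fwrite(dataset$gaze, file.path(dir, "gaze.tsv"), sep = "\t")
  }
  p <- dataset$params
  p$aois <- list(eyes = as.numeric(p$aois$eyes), face = as.numeric(p$aois$face),
                 screen = p$aois$screen)
  gt <- list(params = p[setdiff(names(p), "")],
             cohort = dataset$participants,
             trials = lapply(dataset$schedules, function(s)
               s[, c("aoi", "start_sample", "n_samples")]))
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
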