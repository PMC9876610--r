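# Questionnaire scoring, standardization/grouping, trial metrics, epoch
# curves and exclusion accounting.

test_that("SPIN scoring sums items and hits scale extremes", {
  expect_equal(score_spin(matrix(4, 1, 17)), 68L)
  expect_equal(score_spin(matrix(0, 1, 17)), 0L)
  expect_equal(score_spin(matrix(rep(c(0, 2, 4), c(5, 7, 5)), 1, 17)), 34L)
  expect_error(score_spin(matrix(5, 1, 17)), "0..4")
  expect_error(score_spin(matrix(1, 1, 16)), "17 item")
  m <- matrix(1, 1, 17); m[1, 3] <- NA
  expect_error(score_spin(m), "missing")
})

test_that("AQ scoring respects the reverse key in both systems", {
  key <- aq_default_key()
  expect_length(key, 50)
  # every item at the agree-keyed extreme: 4 on agree items, 1 on reverse
  resp <- matrix(ifelse(key, 4, 1), 1, 50, byrow = FALSE)
  sc <- score_aq(resp, key)
  expect_equal(sc$aq4, 200L)
  expect_equal(sc$aq_binary, 50L)
  # every item at the opposite extreme gives the scale minima
  resp0 <- matrix(ifelse(key, 1, 4), 1, 50)
  sc0 <- score_aq(resp0, key)
  expect_equal(sc0$aq4, 50L)
  expect_equal(sc0$aq_binary, 0L)
  # a slight endorsement (3 on agree-keyed) scores 1 dichotomously
  resp3 <- resp0; resp3[1, which(key)[1]] <- 3
  expect_equal(score_aq(resp3, key)$aq_binary, 1L)
  expect_error(score_aq(resp[, 1:49]), "50 item")
})

test_that("standardization and cutoff groups follow the 26/19 rules", {
  df <- data.frame(aq4 = c(100, 120, 140, 125),
                   aq_binary = c(18, 25, 26, 30),
                   spin = c(10, 18, 19, 40))
  out <- standardize_and_group(df)
  expect_equal(mean(out$z_aq4), 0)
  expect_equal(sd(out$z_aq4), 1)
  expect_equal(mean(out$z_spin), 0)
  expect_identical(as.character(out$aq_group), c("low", "low", "high", "high"))
  expect_identical(as.character(out$spin_group), c("low", "low", "high", "high"))
  # z-scores of z-scores are unchanged (round trip)
  out2 <- standardize_and_group(
    data.frame(aq4 = out$z_aq4, aq_binary = out$aq_binary, spin = out$z_spin))
  expect_equal(out2$z_aq4, out$z_aq4)
  expect_equal(out2$z_spin, out$z_spin)
  expect_error(standardize_and_group(df[1, , drop = FALSE]), "at least 2")
  expect_error(standardize_and_group(
    data.frame(aq4 = c(1, 1), aq_binary = c(1, 1), spin = c(1, 2))),
    "zero variance")
})

test_that("moderator z-levels map back to whole-scale scores", {
  lv <- trait_levels_from_moments(120.35, 14.28)
  expect_identical(lv, c(low = 106L, medium = 120L, high = 135L))
})

test_that("trial metrics implement the first-face-fixation definitions", {
  # eyes 2000 ms + face 3000 ms -> proportion 0.4
  fx <- make_fixations(c(0, 2000), c(2000, 5000), c("eyes", "face"))
  m <- trial_gaze_metrics(fx)
  expect_equal(m$prop_eyes_overall, 0.4)
  # first face fixation on eyes at 300 ms for 150 ms
  fx2 <- make_fixations(c(0, 300, 450), c(250, 450, 2000),
                        c("off", "eyes", "face"))
  m2 <- trial_gaze_metrics(fx2)
  expect_true(m2$first_fix_eyes)
  expect_equal(m2$latency_to_eyes_ms, 300)
  expect_equal(m2$first_fix_duration_ms, 150)
  expect_equal(m2$log_latency, log(300))
  expect_equal(m2$log_duration, log(150))
  # off -> face -> eyes: flag false, duration/latency undefined
  fx3 <- make_fixations(c(0, 300, 800), c(250, 800, 2000),
                        c("off", "face", "eyes"))
  m3 <- trial_gaze_metrics(fx3)
  expect_false(m3$first_fix_eyes)
  expect_true(is.na(m3$first_fix_duration_ms))
  expect_true(is.na(m3$latency_to_eyes_ms))
  # no on-face fixation: undefined with warning
  fx4 <- make_fixations(0, 1000, "off")
  expect_warning(m4 <- trial_gaze_metrics(fx4), "no on-face")
  expect_true(is.na(m4$first_fix_eyes))
})

test_that("participant first-fixation proportion counts valid correct trials", {
  tm <- data.frame(
    participant_id = rep(c("A", "B"), each = 6),
    valid = rep(c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE), 2),
    first_fix_eyes = c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE,
                       TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
  out <- participant_first_fix_proportion(tm)
  expect_equal(out$first_fix_prop[out$participant_id == "A"], 0.2)
  expect_equal(out$first_fix_prop[out$participant_id == "B"], 1.0)
  expect_equal(out$n_valid, c(5L, 5L))
  # invariant to trial order
  perm <- sample(nrow(tm))
  out2 <- participant_first_fix_proportion(tm[perm, ])
  expect_equal(out2[order(out2$participant_id), ],
               out[order(out$participant_id), ], ignore_attr = TRUE)
  # zero valid trials flags the participant
  tm0 <- data.frame(participant_id = "C", valid = FALSE,
                    first_fix_eyes = TRUE)
  out0 <- participant_first_fix_proportion(tm0)
  expect_true(is.na(out0$first_fix_prop) && out0$flagged)
})

test_that("generator first-fixation rate matches its probability parameter", {
  # binomial check at saturating trial counts: logit 0 -> probability 0.5
  p <- sim_params(first_eye_logit = 0, first_eye_b_aq = 0,
                  first_eye_b_spin = 0, first_eye_b_int = 0, seed = 21)
  co <- gen_cohort(2, p)
  hits <- vapply(1:5000, function(s) {
    sch <- gen_trial_schedule(co[1 + s %% 2, ], "neutral", "left", p, seed = s)
    sch$aoi[sch$aoi %in% c("eyes", "face")][1] == "eyes"
  }, TRUE)
  expect_equal(mean(hits), 0.5, tolerance = 0.02)
})

test_that("epoch curve matches definitions and a per-sample recount", {
  # whole trial one eyes fixation: constant 1
  fx <- make_fixations(0, 10000, "eyes")
  ec <- epoch_timecourse(fx)
  expect_true(all(ec$value == 1))
  expect_equal(ec$t_start[1], 0)
  expect_equal(max(ec$t_start) + 250, 10000)
  # eyes 0-5 s then face 5-10 s: step function away from the boundary
  fx2 <- make_fixations(c(0, 5000), c(5000, 10000), c("eyes", "face"))
  ec2 <- epoch_timecourse(fx2)
  expect_true(all(ec2$value[ec2$t_start + 250 <= 5000] == 1))
  expect_true(all(ec2$value[ec2$t_start >= 5000] == 0))
  # randomized fixation intervals equal the 300 Hz per-sample oracle
  set.seed(9)
  for (rep in 1:10) {
    bounds <- sort(sample(seq(0, 10000, by = 10), 9))
    onset <- c(0, bounds); offset <- c(bounds, 10000)
    keep <- offset > onset
    aoi <- sample(c("eyes", "face", "off"), sum(keep), replace = TRUE)
    fx3 <- make_fixations(onset[keep], offset[keep], aoi)
    # grid-aligned windows so interval overlap and sample counts agree
    ec3 <- epoch_timecourse(fx3, window = 250, step = 50)
    or <- oracle_epoch_curve(fx3, window = 250, step = 50,
                             duration_ms = 10000, rate = 100)
    expect_equal(ec3$value, or, tolerance = 1e-9)
  }
})

test_that("whole-trial window reduces the epoch curve to the overall proportion", {
  fx <- make_fixations(c(0, 3000, 7000), c(3000, 7000, 10000),
                       c("eyes", "face", "eyes"))
  ec <- epoch_timecourse(fx, window = 10000, step = 10000)
  expect_equal(nrow(ec), 1)
  expect_equal(ec$value, trial_gaze_metrics(fx)$prop_eyes_overall)
})

test_that("exclusion summary reports counts and one-decimal percentages", {
  mkval <- function(n, n_missing, n_face, n_incorrect) {
    v <- data.frame(missing_gt_30pct = rep(FALSE, n),
                    face_lt_50pct = FALSE, incorrect_response = FALSE)
    if (n_missing > 0) v$missing_gt_30pct[seq_len(n_missing)] <- TRUE
    if (n_face > 0) v$face_lt_50pct[seq_len(n_face)] <- TRUE
    if (n_incorrect > 0) v$incorrect_response[
      n - seq_len(n_incorrect) + 1] <- TRUE
    v$valid <- !(v$missing_gt_30pct | v$face_lt_50pct | v$incorrect_response)
    v
  }
  s <- exclusion_summary(mkval(4800, 874, 0, 0))
  expect_equal(s$pct_invalid, 18.2)
  expect_equal(s$n_invalid, 874)
  expect_equal(exclusion_summary(mkval(100, 0, 0, 0))$pct_invalid, 0.0)
  expect_equal(exclusion_summary(mkval(10, 10, 0, 0))$pct_invalid, 100.0)
  # reasons are non-exclusive
  s2 <- exclusion_summary(mkval(10, 3, 3, 2))
  expect_equal(unname(s2$reasons), c(3, 3, 2))
  expect_equal(s2$n_invalid, 5)
})
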