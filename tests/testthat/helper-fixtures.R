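# Small fixture builders shared across test files.

# A binocular sample table with constant coordinates and a chosen validity
# pattern; timestamps on the 300 Hz grid unless dt is given.
make_samples <- function(n, x = 960, y = 540, valid = rep(TRUE, n),
                         dt = 1000 / 300) {
  x <- rep_len(x, n); y <- rep_len(y, n)
  x[!valid] <- NA_real_; y[!valid] <- NA_real_
  data.frame(t_ms = (seq_len(n) - 1) * dt,
             lx_px = x, ly_px = y, l_valid = valid,
             rx_px = x, ry_px = y, r_valid = valid)
}

# A cyclopean table directly (skips the binocular stage).
make_cyclopean <- function(t, x, y, valid = rep(TRUE, length(t))) {
  x[!valid] <- NA_real_; y[!valid] <- NA_real_
  data.frame(t_ms = t, x_px = x, y_px = y, valid = valid)
}

# A fixation table from (onset, offset, aoi) triples.
make_fixations <- function(onset, offset, aoi, cx = 0, cy = 0) {
  data.frame(onset_ms = onset, offset_ms = offset,
             duration_ms = offset - onset,
             cx = rep_len(cx, length(onset)), cy = rep_len(cy, length(onset)),
             aoi = aoi, stringsAsFactors = FALSE)
}

# Noise-free simulation parameters for round-trip tests.
noise_free_params <- function(...) {
  sim_params(fix_noise_sd = 0, eye_offset_sd = 0, missing_burst_rate = 0,
             accuracy = 1, ...)
}

# Trial-level data for LMM tests generated from an explicit linear model:
# response = b0 + b_aq z_aq + b_spin z_spin + b_int z_aq z_spin +
#            participant intercept + noise. Traits correlated at r.
make_lmm_data <- function(n_participants = 30, n_trials = 10,
                          b = c(b0 = 0, b_aq = 0, b_spin = 0, b_int = 0),
                          ranef_sd = 0.5, resid_sd = 1, r = 0.44,
                          seed = 1) {
  set.seed(seed)
  z1 <- rnorm(n_participants)
  z2 <- r * z1 + sqrt(1 - r^2) * rnorm(n_participants)
  u <- rnorm(n_participants, 0, ranef_sd)
  sex <- sample(c("female", "male"), n_participants, replace = TRUE)
  emos <- c("angry", "fearful", "happy", "sad", "neutral")
  rows <- lapply(seq_len(n_participants), function(i) {
    emotion <- rep_len(emos, n_trials)
    mu <- b["b0"] + b["b_aq"] * z1[i] + b["b_spin"] * z2[i] +
      b["b_int"] * z1[i] * z2[i] + u[i]
    data.frame(participant_id = sprintf("P%03d", i),
               z_aq4 = z1[i], z_spin = z2[i], sex = sex[i],
               emotion = emotion,
               y = mu + rnorm(n_trials, 0, resid_sd))
  })
  do.call(rbind, rows)
}
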