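# Mixed-model fitting, simple slopes, and the cluster-based permutation
# test, each against an independent oracle where one exists.

test_that("zero random-intercept variance reduces the LMM to OLS", {
  d <- make_lmm_data(20, 8, b = c(b0 = 1, b_aq = 0.3, b_spin = 0.2,
                                  b_int = 0.1),
                     ranef_sd = 0, resid_sd = 1, seed = 4)
  fit <- suppressMessages(suppressWarnings(fit_gaze_lmm(d, "y")))
  d$emotion <- factor(d$emotion)
  d$sex <- factor(d$sex)
  ols <- lm(y ~ z_aq4 * z_spin * emotion + sex, data = d,
            contrasts = list(emotion = contr.sum(5), sex = contr.sum(2)))
  b_lmm <- lme4::fixef(fit$fit)
  b_ols <- coef(ols)
  expect_equal(unname(b_lmm), unname(b_ols), tolerance = 1e-6)
})

test_that("the LMM recovers an injected social-anxiety slope", {
  ests <- vapply(1:30, function(s) {
    d <- make_lmm_data(30, 10, b = c(b0 = 0, b_aq = 0, b_spin = 0.2,
                                     b_int = 0),
                       ranef_sd = 0.3, resid_sd = 0.5, seed = 1000 + s)
    fit <- suppressMessages(suppressWarnings(fit_gaze_lmm(d, "y")))
    unname(lme4::fixef(fit$fit)["z_spin"])
  }, 0)
  expect_lt(abs(mean(ests) - 0.2), 4 * sd(ests) / sqrt(30))
})

test_that("simple slopes follow the closed form and the recentring oracle", {
  d <- make_lmm_data(25, 8, b = c(b0 = 0, b_aq = 0.1, b_spin = 0.1,
                                  b_int = 0.12),
                     seed = 7)
  fit <- fit_gaze_lmm(d, "y")
  b <- lme4::fixef(fit$fit)
  ss <- simple_slopes(fit, levels = c(-1, 0, 1))
  # closed form: slope(a) = b_spin + a * b_interaction
  expect_equal(ss$B, unname(b["z_spin"] + c(-1, 0, 1) * b["z_aq4:z_spin"]))
  expect_identical(ss$label, c("low", "medium", "high"))
  # zero interaction: identical slopes at all levels
  b0 <- b; # coefficient arithmetic check without refitting
  expect_equal(ss$B[2], unname(b["z_spin"]))
  # recentring oracle: slope at a equals z_spin coefficient after shifting
  for (a in c(-1, 1)) {
    d2 <- d; d2$z_aq4 <- d2$z_aq4 - a
    fit2 <- fit_gaze_lmm(d2, "y")
    expect_equal(ss$B[ss$level == a],
                 unname(lme4::fixef(fit2$fit)["z_spin"]), tolerance = 1e-8)
    expect_equal(ss$SE[ss$level == a],
                 unname(sqrt(diag(as.matrix(vcov(fit2$fit)))["z_spin"])),
                 tolerance = 1e-6)
  }
  expect_error(simple_slopes(fit, emotion = "bored"), "unknown emotion")
})

test_that("slope labels and standardized slopes are consistent", {
  d <- make_lmm_data(20, 6, b = c(b0 = 0, b_aq = 0, b_spin = 0.3, b_int = 0),
                     seed = 11)
  fit <- fit_gaze_lmm(d, "y")
  ss <- simple_slopes(fit)
  expect_equal(ss$beta, ss$B * sd(d$z_spin) / sd(d$y), tolerance = 1e-12)
  # interaction absent from the model errors
  d$z <- d$z_aq4
  fit_noint <- lmerTest::lmer(y ~ z_spin + (1 | participant_id), data = d)
  obj <- structure(list(fit = fit_noint, data = d, response = "y",
                        df_method = "Satterthwaite", converged = TRUE),
                   class = "gaze_lmm")
  expect_error(simple_slopes(obj), "z_aq4:z_spin")
})

test_that("F statistics are invariant to row order", {
  d <- make_lmm_data(15, 6, b = c(b0 = 0, b_aq = 0.2, b_spin = 0.2,
                                  b_int = 0.1), seed = 3)
  fit1 <- fit_gaze_lmm(d, "y")
  set.seed(1); fit2 <- fit_gaze_lmm(d[sample(nrow(d)), ], "y")
  expect_equal(lmm_term_tests(fit1)$F, lmm_term_tests(fit2)$F,
               tolerance = 1e-6)
})

test_that("identical groups give a flat t trace and no clusters", {
  set.seed(14)
  X <- matrix(rnorm(5 * 12), 5)
  curves <- rbind(X, X)
  res <- cluster_permutation(curves, rep(c("a", "b"), each = 5),
                             n_perm = 200, seed = 2)
  expect_equal(max(abs(res$t)), 0, tolerance = 1e-12)
  expect_equal(nrow(res$clusters), 0)
})

test_that("cluster permutation matches exhaustive enumeration on small instances", {
  set.seed(33)
  for (rep in 1:3) {
    curves <- rbind(matrix(rnorm(3 * 10, 1.5), 3), matrix(rnorm(3 * 10), 3))
    g <- rep(c("hi", "lo"), each = 3)
    res <- cluster_permutation(curves, g, method = "exact")
    orc <- oracle_cluster_p(curves, g)
    expect_equal(nrow(res$clusters), length(orc$masses))
    if (nrow(res$clusters) > 0) {
      expect_equal(res$clusters$mass, orc$masses, tolerance = 1e-9)
      expect_equal(res$clusters$p, orc$p, tolerance = 1e-12)
      expect_equal(res$clusters$start,
                   as.integer(vapply(orc$bounds, `[`, 0, 1)))
    }
    expect_equal(sort(res$null_max), sort(orc$null_max), tolerance = 1e-9)
    # Monte-Carlo p approximates the exact p within sampling error
    if (nrow(res$clusters) > 0) {
      mc <- cluster_permutation(curves, g, n_perm = 2000, seed = 5,
                                method = "montecarlo")
      se <- sqrt(res$clusters$p[1] * (1 - res$clusters$p[1]) / 2000)
      expect_lt(abs(mc$clusters$p[1] - res$clusters$p[1]), 4 * se + 1e-3)
    }
  }
})

test_that("an injected sustained group difference is detected as one cluster", {
  set.seed(88)
  hits <- 0
  for (rep in 1:20) {
    n <- 20
    curves <- rbind(matrix(rnorm(n * 30), n), matrix(rnorm(n * 30), n))
    curves[1:n, 8:16] <- curves[1:n, 8:16] + 2   # 2 pooled SDs, epochs 8-16
    res <- cluster_permutation(curves, rep(c("hi", "lo"), each = n),
                               n_perm = 500, seed = rep)
    sig <- res$clusters[res$clusters$p < 0.05, ]
    if (nrow(sig) >= 1 && any(sig$start <= 16 & sig$end >= 8)) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("cluster permutation validates its inputs", {
  curves <- matrix(rnorm(20), 4)
  expect_error(cluster_permutation(curves, c("a", "a", "a", "b")),
               "at least 2")
  expect_error(cluster_permutation(curves, rep("a", 4)), "2 levels")
  expect_warning(cluster_permutation(rbind(curves, curves),
                                     rep(c("a", "b"), each = 4),
                                     n_perm = 50, seed = 1), "coarse")
})

test_that("undefined epochs are excluded pairwise, not imputed", {
  set.seed(91)
  curves <- rbind(matrix(rnorm(4 * 6), 4), matrix(rnorm(4 * 6, 3), 4))
  curves[1:3, 2] <- NA  # only one usable member in group 1 at epoch 2
  res <- cluster_permutation(curves, rep(c("a", "b"), each = 4),
                             n_perm = 100, seed = 1)
  expect_true(is.na(res$t[2]))
  expect_false(anyNA(res$t[-2]))
})

test_that("log-latency slope sign agrees with a rank regression of raw latency", {
  # monotone transform: the direction of the social-anxiety effect on
  # latency must not depend on analysing log(latency) vs rank(latency)
  d <- gen_dataset(sim_params(n_participants = 50, n_blocks = 2,
                              trials_per_block = 20,
                              latency_b_spin = 0.3, latency_b_int = 0,
                              first_eye_b_int = 0, dur_b_spin = 0,
                              dur_b_int = 0, avoidance_effect = 0,
                              seed = 71), rasterize = FALSE)
  fx <- dataset_truth_fixations(d)
  man <- d$manifest
  val <- man[, c("participant_id", "block", "trial")]
  val$valid <- TRUE
  val$missing_gt_30pct <- FALSE; val$face_lt_50pct <- FALSE
  val$incorrect_response <- FALSE
  tm <- trial_metrics_table(fx, val)
  scored <- standardize_and_group(d$participants)
  trials <- merge(merge(tm, scored, by = "participant_id"),
                  man[, c("participant_id", "block", "trial", "emotion")],
                  by = c("participant_id", "block", "trial"))
  sub <- trials[!is.na(trials$log_latency), ]
  fit <- suppressMessages(suppressWarnings(fit_gaze_lmm(sub, "log_latency")))
  b_log <- lme4::fixef(fit$fit)["z_spin"]
  sub$rank_latency <- rank(sub$latency_to_eyes_ms)
  b_rank <- coef(lm(rank_latency ~ z_aq4 * z_spin, data = sub))["z_spin"]
  expect_gt(b_log, 0)
  expect_identical(sign(unname(b_log)), sign(unname(b_rank)))
})

test_that("analysis battery runs end to end and is deterministic", {
  p <- sim_params(n_participants = 10, n_blocks = 1, trials_per_block = 10,
                  seed = 17)
  d <- gen_dataset(p, rasterize = FALSE)
  fx <- data.table::rbindlist(lapply(names(d$schedules), function(k) {
    parts <- strsplit(k, "_")[[1]]
    cbind(data.frame(participant_id = parts[1], block = as.integer(parts[2]),
                     trial = as.integer(parts[3])),
          schedule_fixations(d$schedules[[k]]))
  }))
  val <- merge(d$manifest, data.frame(missing_fraction = 0), by = NULL)
  val$valid <- val$correct
  val$missing_gt_30pct <- FALSE; val$face_lt_50pct <- FALSE
  val$incorrect_response <- !val$correct
  tm <- trial_metrics_table(fx, val)
  scored <- standardize_and_group(d$participants)
  trials <- merge(tm, scored, by = "participant_id")
  cv <- participant_epoch_curves(fx, val, step = 250)
  cfg <- default_config()
  cfg$permutation$n_perm <- 200
  b1 <- analyze_all(trials, scored, cv, cfg, seed = 5)
  b2 <- analyze_all(trials, scored, cv, cfg, seed = 5)
  expect_equal(b1, b2)
  expect_named(b1, c("prop_eyes_overall", "first_fix_eyes", "log_duration",
                     "log_latency", "cluster_aq", "cluster_spin",
                     "exclusions"))
  expect_equal(nrow(b1$prop_eyes_overall$slopes), 3)
  # results bundle serializes
  path <- withr::local_tempfile(fileext = ".json")
  write_results_bundle(b1, path)
  expect_true(file.size(path) > 0)
})
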