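#!/usr/bin/env Rscript
# Figures for the analysis battery: simple-slope plots of social anxiety
# at the three autistic-trait levels per model, the main-effect scatter
# for first-fixation duration, and the group time-course plot with
# significant-cluster bars. Purely presentational: every number is read
# from the results bundle or the derived tables.

suppressMessages({
  library(gazetraits)
  library(optparse)
  library(ggplot2)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--data", type = "character", default = "scratch/gaze_data"),
  make_option("--derived", type = "character", default = "scratch/derived")
)))

dir.create("results/figures", recursive = TRUE, showWarnings = FALSE)
trials <- as.data.frame(
  data.table::fread(file.path(opts$derived, "trial_metrics.csv")))
curves <- readRDS(file.path(opts$derived, "curves.rds"))
bundle <- jsonlite::read_json("results/results_bundle.json",
                              simplifyVector = TRUE)
valid <- trials[trials$valid, ]

# simple-slope fans: predicted response vs z_spin at the three AQ levels
slope_fig <- function(nm, ylab) {
  ss <- bundle[[nm]]$slopes
  grid <- expand.grid(z_spin = seq(-2, 2, length.out = 20),
                      label = ss$label)
  grid$B <- ss$B[match(grid$label, ss$label)]
  resp <- if (nm == "first_fix_eyes") "first_fix_eyes" else nm
  base <- mean(as.numeric(valid[[resp]]), na.rm = TRUE)
  grid$pred <- base + grid$B * grid$z_spin
  grid$label <- factor(grid$label, levels = c("low", "medium", "high"))
  ggplot(grid, aes(z_spin, pred, colour = label)) +
    geom_line(linewidth = 0.9) +
    labs(x = "Social anxiety (z-SPIN)", y = ylab,
         colour = "Autistic traits") +
    theme_minimal()
}
ggsave("results/figures/slopes_first_fix.png",
       slope_fig("first_fix_eyes", "P(first fixation on eyes)"),
       width = 5, height = 3.5, dpi = 150)
ggsave("results/figures/slopes_log_duration.png",
       slope_fig("log_duration", "log first-fixation duration"),
       width = 5, height = 3.5, dpi = 150)
ggsave("results/figures/slopes_log_latency.png",
       slope_fig("log_latency", "log latency to eyes"),
       width = 5, height = 3.5, dpi = 150)

# main effect of social anxiety on log first-fixation duration
p_dur <- ggplot(valid[!is.na(valid$log_duration), ],
                aes(z_spin, log_duration)) +
  geom_point(alpha = 0.2, size = 0.7) +
  geom_smooth(method = "lm", formula = y ~ x, colour = "steelblue") +
  labs(x = "Social anxiety (z-SPIN)",
       y = "log first-fixation duration on eyes") +
  theme_minimal()
ggsave("results/figures/duration_main_effect.png", p_dur,
       width = 5, height = 3.5, dpi = 150)

# group time courses with significant-cluster bars
ds_part <- read.csv(file.path(opts$data, "participants.csv"))
scored <- standardize_and_group(ds_part)
curve_fig <- function(group_col, cl, title) {
  g <- scored[[group_col]][match(rownames(curves$curves),
                                 scored$participant_id)]
  df <- do.call(rbind, lapply(c("low", "high"), function(lv) {
    m <- curves$curves[g == lv, , drop = FALSE]
    data.frame(t = curves$t_mid / 1000, group = lv,
               mean = colMeans(m, na.rm = TRUE),
               se = apply(m, 2, sd, na.rm = TRUE) / sqrt(colSums(!is.na(m))))
  }))
  p <- ggplot(df, aes(t, mean, colour = group, fill = group)) +
    geom_ribbon(aes(ymin = mean - se, ymax = mean + se), alpha = 0.2,
                colour = NA) +
    geom_line() +
    labs(x = "Time from face onset (s)",
         y = "Proportional eye-looking", title = title,
         colour = NULL, fill = NULL) +
    theme_minimal()
  cls <- cl$clusters
  if (is.data.frame(cls) && nrow(cls) > 0) {
    sig <- cls[cls$p <= 0.05, , drop = FALSE]
    if (nrow(sig) > 0) {
      p <- p + annotate("segment",
                        x = curves$t_mid[sig$start] / 1000,
                        xend = curves$t_mid[sig$end] / 1000,
                        y = 0.02, yend = 0.02,
                        linewidth = 1.5, colour = "grey30")
    }
  } else {
    message(title, ": no significant clusters")
  }
  p
}
ggsave("results/figures/timecourse_aq_groups.png",
       curve_fig("aq_group", bundle$cluster_aq,
                 "High vs low autistic traits"),
       width = 6, height = 3.5, dpi = 150)
ggsave("results/figures/timecourse_spin_groups.png",
       curve_fig("spin_group", bundle$cluster_spin,
                 "High vs low social anxiety"),
       width = 6, height = 3.5, dpi = 150)
message("Figures written to results/figures/")
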