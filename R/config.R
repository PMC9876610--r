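# Pipeline configuration: one nested list, YAML round-trippable, with
# every default equal to the analysis constants of the task this pipeline
# models (75 ms interpolation gap, 30%/50% exclusion thresholds, 250 ms
# epochs, AQ/SPIN cutoffs 26/19, moderator levels -1/0/+1).

#' Default pipeline configuration
#'
#' @param seed global seed stored in the config.
#' @return nested list of class `gaze_config`.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    trial = list(duration_ms = 10000, sample_rate = 300),
    interpolation = list(max_gap_ms = 75),
    fixation = list(method = "idt",
                    dispersion_px = px_per_degree(),
                    min_duration_ms = 60),
    validity = list(missing_max = 0.30, face_min = 0.50,
                    face_time_from = "fixations"),
    epochs = list(window_ms = 250, step_ms = 50),
    groups = list(aq_cutoff = 26, spin_cutoff = 19),
    slopes = list(levels = c(-1, 0, 1)),
    permutation = list(n_perm = 1000, cluster_alpha = 0.05),
    seed = as.integer(seed)
  ), class = "gaze_config")
}

#' Read a pipeline configuration from YAML
#'
#' Missing fields fall back to the defaults of [default_config()].
#'
#' @param path YAML file.
#' @return `gaze_config` list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  base <- unclass(default_config())
  merged <- utils::modifyList(base, user)
  structure(merged, class = "gaze_config")
}

#' Write a pipeline configuration to YAML
#'
#' @param config a `gaze_config` list.
#' @param path output file.
#' @return (invisibly) the path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
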