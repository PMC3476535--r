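#' Pipeline configuration
#'
#' Collects every tunable of the analysis chain with validated defaults.
#' Unknown names are rejected; the object round-trips losslessly through
#' [write_config()] / [read_config()].
#'
#' @param ... Name-value overrides of the defaults listed below.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    ## study / generator
    subjects = 8L, reps = 20L, n_channels = 64L,
    fs = 512, fs_aux = 1000,
    trial_mean = 3, trial_cv = 0.1, pause = 5,
    shift_mm = 15, noise_rms = 1, line_amp = 0.5, drift_rms = 10,
    ## preprocessing
    hp_cutoff = 1, hp_order = 4,
    std_limit = 1000, kurt_z = 3, r_limit = 0.4,
    max_uncorrelated = 0.001, corr_window_s = 1, n_neighbors = 4L,
    ## mixture ICA
    n_models = 2L, n_components = 16L, ica_max_iter = 300L,
    ica_tol = 1e-7, ica_max_samples = 100000L, ica_n_scale = 3L,
    ica_restarts = 3L,
    ## source space
    k_clusters = 10L, location_weight = 3, n_map_pc = 10L,
    retain_fraction = 0.75,
    ## time-frequency
    fmin = 3, fmax = 150, n_freqs = 220L,
    tf_window = 0.5, tf_step = 0.025,
    baseline = c(-1, -0.5),
    alpha = 0.05, n_boot = 200L,
    ## decoding
    reduce_factor = 10L, cv_folds = 10L, exclude_visual = TRUE,
    paper_mode = FALSE,
    write_edf = FALSE)
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown))
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  cfg[names(ov)] <- ov
  validate_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Validate a pipeline configuration
#' @param cfg A configuration list.
#' @return Invisibly, `cfg`.
#' @export
validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop("invalid configuration: ", msg)
  chk(cfg$alpha > 0 && cfg$alpha <= 1, "alpha must be in (0, 1]")
  chk(cfg$fs > 0 && cfg$fs_aux > 0, "sampling rates must be positive")
  chk(cfg$hp_cutoff > 0 && cfg$hp_cutoff < cfg$fs / 2,
      "high-pass cutoff must lie in (0, fs/2)")
  chk(cfg$subjects >= 1 && cfg$reps >= 0, "subjects/reps out of range")
  chk(cfg$n_models >= 1, "n_models must be >= 1")
  chk(cfg$n_components >= 2 && cfg$n_components <= cfg$n_channels,
      "n_components must be in [2, n_channels]")
  chk(cfg$fmin > 0 && cfg$fmax > cfg$fmin && cfg$fmax < cfg$fs / 2,
      "frequency grid must satisfy 0 < fmin < fmax < fs/2")
  chk(cfg$n_freqs >= 2, "n_freqs must be >= 2")
  chk(length(cfg$baseline) == 2 && cfg$baseline[1] < cfg$baseline[2] &&
        cfg$baseline[2] <= 0, "baseline must be a pre-onset window")
  chk(cfg$n_boot >= 1, "n_boot must be positive")
  chk(cfg$cv_folds >= 2, "cv_folds must be >= 2")
  chk(cfg$reduce_factor >= 1, "reduce_factor must be >= 1")
  chk(cfg$std_limit > 0 && cfg$kurt_z > 0, "rejection thresholds invalid")
  chk(cfg$r_limit > 0 && cfg$r_limit < 1, "r_limit must be in (0, 1)")
  chk(cfg$max_uncorrelated >= 0 && cfg$max_uncorrelated < 1,
      "max_uncorrelated must be in [0, 1)")
  invisible(cfg)
}

#' Write / read a configuration as YAML
#' @param cfg A `pipeline_config`.
#' @param path YAML file path.
#' @return `write_config` invisibly returns `path`; `read_config` the
#'   validated configuration.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}
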