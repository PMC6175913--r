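# Flat key-value project configuration. Unknown keys are rejected; the
# snapshot is embedded in every pipeline output artifact.

.configDefaults <- list(
  alpha = 0.05,             # rank-sum significance level for PI/LI
  pi_threshold = 0.25,      # stability gate: keep features with PI < 0.25
  top_k = 5L,               # features selected per selector
  auc_cv_iterations = 100L, # per-feature LDA CV iterations (PI-AUC map)
  sfs_cv_iterations = 10L,  # QDA CV iterations inside the SFS objective
  cv_folds = 3L,
  subgraph_radius_um = 200,
  haralick_window_px = 64L,
  haralick_stride_px = 32L,
  haralick_gray_levels = 64L,
  min_lumen_area_px = 30,   # at the 4 um/px segmentation scale
  smoothing_window = 5L,    # boundary moving-average window (vertices)
  seg_mpp = 4,              # segmentation scale (5X equivalent)
  feat_mpp = 16,            # feature-extraction scale (1.25X equivalent)
  od_threshold = 0.15,      # stain-normalization background OD threshold
  angle_percentile_low = 1,
  angle_percentile_high = 99,
  seed = 1L
)

#' Default project configuration
#'
#' Returns the flat key-value configuration holding every tunable constant
#' of the pipeline (significance level, PI threshold 0.25, top-k 5, CV
#' counts 100 and 10 x 3-fold, sub-graph radius, Haralick window/levels,
#' segmentation minima, magnification protocol and seed).
#'
#' @param ... named overrides of default keys; unknown keys are rejected.
#' @return A named list of configuration values.
#' @export
defaultConfig <- function(...) {
  over <- list(...)
  validateConfig(utils::modifyList(.configDefaults, over), names(over))
}

#' Validate a configuration list
#'
#' @param config named list of configuration values.
#' @param newKeys optional keys being introduced (used internally).
#' @return The validated config (invisibly identical to the input).
#' @export
validateConfig <- function(config, newKeys = names(config)) {
  unknown <- setdiff(newKeys, names(.configDefaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  missing <- setdiff(names(.configDefaults), names(config))
  if (length(missing))
    stop("missing config key(s): ", paste(missing, collapse = ", "))
  config
}

#' Read / write a configuration file
#'
#' Configurations are stored as a flat YAML key-value document.
#'
#' @param path file path.
#' @param config configuration list (for `writeConfig`).
#' @return `readConfig` returns the validated configuration list.
#' @export
readConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  validateConfig(utils::modifyList(.configDefaults, cfg), names(cfg))
}

#' @rdname readConfig
#' @export
writeConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

configSnapshotLines <- function(config) {
  c(sprintf("# glandstab %s", as.character(utils::packageVersion("glandstab"))),
    vapply(names(config), function(k)
      sprintf("# config %s: %s", k, paste(config[[k]], collapse = ",")),
      character(1)))
}
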