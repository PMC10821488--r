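# End-to-end orchestration: raw streams (or a simulated cohort) ->
# kinematics -> segments -> features -> repeated-split benchmark ->
# importance table, with a single YAML config and one root seed feeding
# named substreams.

#' Process one trial up to its feature matrix
#'
#' @param wheel Wheel [imu_stream].
#' @param frame Frame [imu_stream] or `NULL` (required for S2).
#' @param annotations An [annotation_track].
#' @param geometry A [wheelchair_geometry].
#' @param variant `"S1"` or `"S2"`.
#' @param seg_cfg A [segmentation_config].
#' @return List with `kin`, `segments` (labelled) and `features`.
#' @export
process_trial <- function(wheel, frame, annotations, geometry,
                          variant = c("S1", "S2"),
                          seg_cfg = segmentation_config()) {
  variant <- match.arg(variant)
  kin <- compute_kinematics(wheel, if (variant == "S2") frame else NULL,
                            geometry, variant)
  segs <- label_segments(detect_segments(kin, seg_cfg), annotations)
  raw <- attr(kin, "streams")[[if (variant == "S1") "wheel" else "frame"]]
  fm <- build_feature_matrix(segs, kin, raw, variant)
  list(kin = kin, segments = segs, features = fm)
}

#' Feature matrix for a whole simulated cohort
#'
#' Processes every trial with the requested sensor configuration and
#' stacks the per-segment feature rows. Per-trial segment tables and
#' moving-speed statistics are attached as attributes `segments` and
#' `speed_stats`.
#'
#' @param cohort A `simulated_cohort` from [generate_cohort].
#' @param geometry A [wheelchair_geometry].
#' @param variant `"S1"` or `"S2"`.
#' @param seg_cfg A [segmentation_config].
#' @return A `feature_matrix` covering all labelled segments.
#' @export
cohort_feature_matrix <- function(cohort, geometry = wheelchair_geometry(),
                                  variant = c("S1", "S2"),
                                  seg_cfg = segmentation_config()) {
  variant <- match.arg(variant)
  parts <- lapply(cohort, function(trial) {
    res <- process_trial(trial$wheel, trial$frame, trial$annotations,
                         geometry, variant, seg_cfg)
    moving <- abs(res$kin$speed) > seg_cfg$speed_threshold
    stats <- data.frame(
      participant_id = trial$participant_id,
      mean_moving_speed = mean(abs(res$kin$speed[moving])),
      distance = attr(reconstruct_path(res$kin), "distance"),
      duration = max(res$kin$time))
    list(fm = res$features, segments = res$segments, stats = stats)
  })
  fm <- do.call(rbind, lapply(parts, `[[`, "fm"))
  structure(fm, variant = variant, predictors = feature_names(),
            segments = do.call(rbind, lapply(parts, `[[`, "segments")),
            speed_stats = do.call(rbind, lapply(parts, `[[`, "stats")),
            class = c("feature_matrix", "data.frame"))
}

#' @noRd
default_config_ <- function() {
  list(participants = 24L, seed = 1L, variants = c("S1", "S2"),
       n_splits = 25L, test_fraction = 0.2, prune_threshold = 0.7,
       speed_threshold = 0.1, min_duration = 2,
       wheel_diameter_m = 0.6, track_width_m = 0.56, sensor_side = "right",
       gyro_noise_sd = 0.5, accel_noise_sd = 0.05, gyro_bias_range = 2,
       class_contrast = 1, out_dir = NULL)
}

#' Run the full detection pipeline on a simulated cohort
#'
#' Generates the cohort, reconstructs kinematics, segments and labels the
#' movement, builds the 56-predictor feature matrices and runs the
#' repeated-split benchmark and importance analysis for each requested
#' sensor configuration. All randomness derives from the single `seed`
#' entry through named substreams, so identical configs give identical
#' reports.
#'
#' @param config A named list, or path to a YAML file, overriding the
#'   defaults: `participants`, `seed`, `variants`, `n_splits`,
#'   `test_fraction`, `prune_threshold`, `speed_threshold`,
#'   `min_duration`, `wheel_diameter_m`, `track_width_m`, `sensor_side`,
#'   `gyro_noise_sd`, `accel_noise_sd`, `gyro_bias_range`,
#'   `class_contrast`, `out_dir`.
#' @return List with per-variant `reports` and `importance` tables, the
#'   stacked `features`, the resolved `config`, and `cohort` summary
#'   statistics.
#' @export
run_end_to_end <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_config_(), config)
  bad <- setdiff(cfg$variants, c("S1", "S2"))
  if (length(bad)) stop("unknown model variant(s): ", paste(bad, collapse = ", "))
  geometry <- wheelchair_geometry(cfg$wheel_diameter_m, cfg$track_width_m,
                                  cfg$sensor_side)
  noise <- imu_noise(cfg$gyro_noise_sd, cfg$accel_noise_sd, cfg$gyro_bias_range)
  seg_cfg <- segmentation_config(cfg$speed_threshold, cfg$min_duration)
  wm_log_("simulating cohort: %d participants, seed %d", cfg$participants, cfg$seed)
  cohort <- generate_cohort(cfg$participants,
                            seed = child_seed_(cfg$seed, "cohort"),
                            geometry = geometry, noise = noise,
                            class_contrast = cfg$class_contrast)
  reports <- list(); importance <- list(); features <- list()
  for (variant in cfg$variants) {
    fm <- cohort_feature_matrix(cohort, geometry, variant, seg_cfg)
    segs <- attr(fm, "segments")
    wm_log_("%s: %d segments (%d active / %d passive / %d unknown), %d feature rows",
            variant, nrow(segs), sum(segs$label == "active"),
            sum(segs$label == "passive"), sum(segs$label == "unknown"),
            nrow(fm))
    rep <- run_benchmark(fm, n_splits = cfg$n_splits,
                         seed = child_seed_(cfg$seed, paste0("bench", variant)),
                         test_fraction = cfg$test_fraction,
                         prune_threshold = cfg$prune_threshold)
    wm_log_("%s: %d/56 predictors retained, mean F1 %.3f",
            variant, length(rep$retained), rep$means["f1"])
    imp <- feature_importance(fm, rep$retained,
                              seed = child_seed_(cfg$seed, paste0("imp", variant)))
    reports[[variant]] <- rep
    importance[[variant]] <- imp
    features[[variant]] <- fm
  }
  result <- list(reports = reports, importance = importance,
                 features = features, config = cfg,
                 cohort_stats = attr(features[[1L]], "speed_stats"))
  if (!is.null(cfg$out_dir)) write_run_artifacts_(result, cfg$out_dir)
  result
}

#' @noRd
write_run_artifacts_ <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (variant in names(result$reports)) {
    rep <- result$reports[[variant]]
    utils::write.csv(rep$per_split,
                     file.path(out_dir, paste0("per_split_", variant, ".csv")),
                     row.names = FALSE)
    utils::write.csv(result$importance[[variant]],
                     file.path(out_dir, paste0("importance_", variant, ".csv")),
                     row.names = FALSE)
    utils::write.csv(result$features[[variant]],
                     file.path(out_dir, paste0("features_", variant, ".csv")),
                     row.names = FALSE)
  }
  summary <- list(
    config = result$config[setdiff(names(result$config), "out_dir")],
    means = lapply(result$reports, function(r) as.list(r$means)),
    retained = lapply(result$reports, function(r) r$retained))
  yaml::write_yaml(summary, file.path(out_dir, "manifest.yaml"))
  jsonlite::write_json(lapply(result$reports, function(r)
    list(means = as.list(r$means), n_splits = r$n_splits,
         retained = length(r$retained))),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
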