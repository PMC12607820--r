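# End-to-end orchestration: simulate -> analyze-video -> analyze-cop ->
# validate, driven by a YAML config or an equivalent named list.  Every
# stage writes plain CSV artifacts plus a JSON run manifest (config
# echo, package version, seeds, input checksums) so a run can be
# reproduced from its output directory alone.

default_config <- function() {
  list(
    seed = 1L,
    out_dir = "swaybalance_run",
    cohort = list(n_cp = 5L, n_control = 5L, cp_amplitude_multiplier = 2,
                  condition_multipliers = c(1, 1.3, 1.6, 2),
                  coupling_noise_sd = 1, tremor_amplitude = 0.5,
                  pixel_to_mm = 2),
    sway = list(amplitude_x = 2, amplitude_y = 3, bandwidth_hz = 2,
                duration_s = 30, rate_hz = 30),
    render = list(frame_width = 64, frame_height = 96,
                  silhouette_half_width = 8, silhouette_half_height = 14,
                  fps = 30),
    video = list(threshold = 0.15, morph_open_radius = 0,
                 morph_close_radius = 2, min_component_area = 20,
                 write_avi = FALSE),
    cop = list(order = 4L, cutoff_hz = 10, mode = "zero_phase", rate_hz = 100)
  )
}

merge_config <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]])) {
      base[[k]] <- merge_config(base[[k]], override[[k]])
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

#' Load a pipeline run configuration
#'
#' Reads a YAML file (or accepts a named list) and fills unspecified
#' fields from the defaults, which use the standard protocol values:
#' detection threshold 0.15, filter order 4, cutoff 10 Hz, plate rate
#' 100 Hz, 30 s trials.
#'
#' @param config Path to a YAML file, a named list of overrides, or
#'   `NULL` for pure defaults.
#' @export
load_run_config <- function(config = NULL) {
  base <- default_config()
  if (is.null(config)) return(base)
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop(sprintf("config file not found: %s", config), call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop_param("config", "must be a YAML path or a named list")
  merge_config(base, config)
}

write_manifest <- function(dir, config, inputs = character(0), extra = list()) {
  manifest <- c(list(
    package = "swaybalance",
    version = as.character(packageVersion("swaybalance")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    input_checksums = as.list(tools::md5sum(inputs))
  ), extra)
  jsonlite::write_json(manifest, file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Simulate a synthetic cohort to disk
#'
#' Generates the paired cohort and writes, per trial, the COP CSV,
#' the ground-truth trajectory CSV, and optionally an uncompressed AVI
#' of the rendered video, plus a `trial_manifest.csv` tying them
#' together.
#'
#' @param config See [load_run_config()].
#' @return The cohort's trial manifest data frame (invisibly), with
#'   file-path columns added.
#' @export
pipeline_simulate <- function(config = NULL) {
  cfg <- load_run_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  spec <- do.call(cohort_spec, c(cfg$cohort, list(seed = cfg$seed)))
  base <- do.call(sway_model_params, c(cfg$sway, list(seed = cfg$seed)))
  rp <- do.call(render_params, cfg$render)
  cohort <- generate_cohort(spec, base, render = rp)
  man <- cohort$manifest
  man$cop_csv <- NA_character_; man$truth_csv <- NA_character_
  man$video_avi <- NA_character_
  for (i in seq_along(cohort$trials)) {
    tr <- cohort$trials[[i]]
    stem <- sprintf("%s_%s", tr$subject_id, tr$condition)
    man$cop_csv[i] <- file.path(cfg$out_dir, paste0(stem, "_cop.csv"))
    write_cop_csv(tr$cop, man$cop_csv[i])
    man$truth_csv[i] <- file.path(cfg$out_dir, paste0(stem, "_truth.csv"))
    write_trajectory_csv(tr$traj, man$truth_csv[i])
    if (isTRUE(cfg$video$write_avi)) {
      man$video_avi[i] <- file.path(cfg$out_dir, paste0(stem, ".avi"))
      write_video_avi(tr$video, man$video_avi[i])
    }
  }
  write.csv(man, file.path(cfg$out_dir, "trial_manifest.csv"), row.names = FALSE)
  write_manifest(cfg$out_dir, cfg, extra = list(stage = "simulate",
                                                n_trials = nrow(man)))
  invisible(man)
}

#' Analyze one video file into a sway-parameter row
#'
#' Loads the video, extracts the silhouette-centroid trajectory and
#' computes the nine sway parameters.  Writes the trajectory CSV
#' alongside the input when `out_trajectory` is given.
#'
#' @param path AVI file path (see [load_video()]).
#' @param roi A [region_of_interest()] or `NULL`.
#' @param cfg A [motion_config()].
#' @param fps Optional frame-rate override.
#' @param keys Named list of identifying columns for the output row.
#' @param out_trajectory Optional path for the extracted trajectory CSV.
#' @return One-row parameter data frame (`Vmean_COMx` ...).
#' @export
pipeline_analyze_video <- function(path, roi = NULL, cfg = motion_config(),
                                   fps = NULL, keys = list(),
                                   out_trajectory = NULL) {
  seq <- load_video(path, fps = fps)
  traj <- extract_com_trajectory(seq, roi = roi, cfg = cfg)
  if (!is.null(out_trajectory)) write_trajectory_csv(traj, out_trajectory)
  sway_parameters_row(compute_sway_parameters(traj), "COM", keys = keys)
}

#' Analyze one COP CSV into a sway-parameter row
#'
#' Loads the recording, applies the Butterworth conditioning and
#' computes the nine sway parameters.
#'
#' @param path COP CSV path (see [load_cop()]).
#' @param spec A [filter_spec()].
#' @param rate_hz Optional declared sampling rate.
#' @param keys Named list of identifying columns for the output row.
#' @return One-row parameter data frame (`Vmean_COPx` ...).
#' @export
pipeline_analyze_cop <- function(path, spec = filter_spec(), rate_hz = NULL,
                                 keys = list()) {
  rec <- load_cop(path, rate_hz = rate_hz)
  rec <- butterworth_lowpass(rec, spec)
  sway_parameters_row(compute_sway_parameters(cop_to_trajectory(rec)),
                      "COP", keys = keys)
}

#' Run the full synthetic pipeline end to end
#'
#' simulate -> analyze every trial's video (in memory unless
#' `video$write_avi` requests the AVI round trip) and COP recording ->
#' validate, writing `image_params.csv`, `cop_params.csv`, the
#' validation report and a run manifest under `out_dir`.
#'
#' @param config See [load_run_config()].
#' @return The [run_validation()] report (invisibly).
#' @export
run_pipeline <- function(config = NULL) {
  cfg <- load_run_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  spec <- do.call(cohort_spec, c(cfg$cohort, list(seed = cfg$seed)))
  base <- do.call(sway_model_params, c(cfg$sway, list(seed = cfg$seed)))
  rp <- do.call(render_params, cfg$render)
  mc <- motion_config(threshold = cfg$video$threshold,
                      morph_open_radius = cfg$video$morph_open_radius,
                      morph_close_radius = cfg$video$morph_close_radius,
                      min_component_area = cfg$video$min_component_area)
  fs <- filter_spec(order = cfg$cop$order, cutoff_hz = cfg$cop$cutoff_hz,
                    mode = cfg$cop$mode)
  cohort <- generate_cohort(spec, base, render = rp)
  img_rows <- list(); cop_rows <- list()
  for (tr in cohort$trials) {
    keys <- list(subject_id = tr$subject_id, group = tr$group,
                 condition = tr$condition)
    video <- tr$video
    if (isTRUE(cfg$video$write_avi)) {
      avi <- file.path(cfg$out_dir, sprintf("%s_%s.avi", tr$subject_id, tr$condition))
      write_video_avi(video, avi)
      video <- suppressMessages(load_video(avi))
    }
    traj <- extract_com_trajectory(video, cfg = mc)
    img_rows[[length(img_rows) + 1L]] <-
      sway_parameters_row(compute_sway_parameters(traj), "COM", keys = keys)
    rec <- butterworth_lowpass(tr$cop, fs)
    cop_rows[[length(cop_rows) + 1L]] <-
      sway_parameters_row(compute_sway_parameters(cop_to_trajectory(rec)),
                          "COP", keys = keys)
  }
  image_params <- do.call(rbind, img_rows)
  cop_params <- do.call(rbind, cop_rows)
  write_parameters_csv(image_params, file.path(cfg$out_dir, "image_params.csv"))
  write_parameters_csv(cop_params, file.path(cfg$out_dir, "cop_params.csv"))
  report <- run_validation(image_params, cop_params)
  write_validation_report(report, file.path(cfg$out_dir, "validation"))
  write_manifest(cfg$out_dir, cfg, extra = list(stage = "all",
                                                n_trials = length(cohort$trials)))
  invisible(report)
}
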