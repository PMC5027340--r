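#' Default end-to-end run configuration
#'
#' Collects every tunable of the pipeline in one list so that each analysis
#' output can embed the full effective configuration and seed for
#' provenance. Units are fixed package-wide: coordinates in mm, times in
#' ms, speeds in m/s, channel ids 0-based row-major.
#'
#' @param seed Master seed; all stage seeds derive from it.
#' @param rows,cols,pitch_mm Array geometry (default 16 x 8 at 2.7 mm —
#'   the 128-channel device layout).
#' @param wavefront `"planar"` or `"focal"`.
#' @param speed_mps,direction_deg,origin_mm,t0_ms Wavefront truth
#'   parameters.
#' @param ari_ms Programmed ARI for synthesis.
#' @param noise_sd_mv Recording noise SD.
#' @param blanking_ms,repol_window_ms Detection windows.
#' @param speed_bounds,min_dt_ms Triangle validity filters.
#' @param wpv_summary `"mean"` or `"median"`.
#' @param var_equal Student's pooled t (TRUE) vs Welch.
#' @param cohort Cohort generator parameters ([cohort_params()]).
#' @param recording_path Optional path of an existing recording header to
#'   analyze instead of synthesizing one.
#' @param cohort_path Optional path of an existing cohort CSV.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, rows = 16, cols = 8, pitch_mm = 2.7,
                       wavefront = c("planar", "focal"),
                       speed_mps = 0.9, direction_deg = 30, origin_mm = c(0, 0),
                       t0_ms = 10, ari_ms = 180, noise_sd_mv = 0.05,
                       blanking_ms = 5, repol_window_ms = c(80, 400),
                       speed_bounds = c(0.1, 5), min_dt_ms = 0.04,
                       wpv_summary = "mean", var_equal = TRUE,
                       cohort = cohort_params(),
                       recording_path = NULL, cohort_path = NULL) {
  structure(list(seed = as.integer(seed), rows = rows, cols = cols,
                 pitch_mm = pitch_mm, wavefront = match.arg(wavefront),
                 speed_mps = speed_mps, direction_deg = direction_deg,
                 origin_mm = origin_mm, t0_ms = t0_ms, ari_ms = ari_ms,
                 noise_sd_mv = noise_sd_mv, blanking_ms = blanking_ms,
                 repol_window_ms = repol_window_ms, speed_bounds = speed_bounds,
                 min_dt_ms = min_dt_ms, wpv_summary = wpv_summary,
                 var_equal = var_equal, cohort = cohort,
                 recording_path = recording_path, cohort_path = cohort_path),
            class = "run_config")
}

config_provenance <- function(config) {
  cfg <- unclass(config)
  cfg$cohort <- if (inherits(cfg$cohort, "cohort_params")) {
    list(n = as.list(cfg$cohort$n),
         map_weeks = cfg$cohort$map_weeks,
         map_meas_sd_mmhg = cfg$cohort$map_meas_sd_mmhg,
         endpoints = lapply(cfg$cohort$endpoints, function(m) as.data.frame(m)),
         postmortem = lapply(cfg$cohort$postmortem, function(m) as.data.frame(m)))
  } else cfg$cohort
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> detect -> conduction mapping -> CHI / ARI ->
#' cohort endpoint report and writes every intermediate artifact as CSV
#' plus a provenance JSON (effective configuration, seed, filter counts)
#' into `out_dir`. Given the same configuration and seed, all machine
#' outputs are byte-identical across reruns; logs go to standard error
#' only. Any stage failure aborts with the stage name in the message.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a named list of result objects and output paths.
#' @export
run_pipeline <- function(config = run_config(), out_dir = "epimapr_out") {
  if (!inherits(config, "run_config")) stop_invalid("config must come from run_config()")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_analysis("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  geometry <- stage("geometry", make_geometry(config$rows, config$cols, config$pitch_mm))

  recording <- if (!is.null(config$recording_path)) {
    if (!file.exists(config$recording_path)) {
      stop_format("recording input not found: %s", config$recording_path)
    }
    stage("read-recording", read_recording(config$recording_path))
  } else {
    truth <- stage("truth", switch(config$wavefront,
      planar = simulate_planar_truth(geometry, config$speed_mps,
                                     config$direction_deg, config$t0_ms),
      focal = simulate_focal_truth(geometry, config$speed_mps,
                                   config$origin_mm, config$t0_ms)))
    stage("synthesize", synthesize_recording(
      truth, ari_ms = config$ari_ms, noise_sd_mv = config$noise_sd_mv,
      seed = config$seed))
  }
  log_msg("INFO", "recording: %d channels x %d samples",
          nrow(recording$signal), ncol(recording$signal))

  amap <- stage("activation", detect_activation_times(
    recording, blanking_ms = config$blanking_ms))
  rmap <- stage("repolarization", detect_repolarization_times(
    recording, amap, repol_window_ms = config$repol_window_ms))
  ari <- stage("ari", compute_ari(amap, rmap))
  field <- stage("conduction", wave_propagation_velocity(
    amap, recording$geometry, speed_bounds = config$speed_bounds,
    min_dt_ms = config$min_dt_ms, summary = config$wpv_summary))
  pm <- stage("phase-map", phase_map(amap, recording$geometry))
  chi <- stage("chi", conduction_heterogeneity_index(pm))

  rej <- table(field$triangles$reason[!field$triangles$valid])
  log_msg("INFO", "channels invalid: %d/%d; triangles rejected: %s",
          sum(!amap$valid), nrow(amap),
          if (length(rej)) paste(sprintf("%s=%d", names(rej), rej), collapse = ", ")
          else "none")

  cohort <- if (!is.null(config$cohort_path)) {
    stage("read-cohort", read_cohort_csv(config$cohort_path))
  } else {
    stage("cohort", generate_cohort(config$cohort, seed = config$seed + 1L))
  }
  report <- stage("endpoints", endpoint_report(cohort, var_equal = config$var_equal))
  traj <- stage("map-trajectory", map_trajectory_summary(cohort))

  p <- function(f) file.path(out_dir, f)
  write_geometry_csv(geometry, p("geometry.csv"))
  write_map_csv(amap, p("activation_map.csv"))
  write_map_csv(rmap, p("repolarization_map.csv"))
  write_map_csv(ari, p("ari_map.csv"))
  write_conduction_csv(field, p("conduction_triangles.csv"))
  utils::write.csv(data.frame(wpv_mps = field$wpv_mps, sd_mps = field$sd_mps,
                              n_valid = field$n_valid, summary = field$summary),
                   p("wpv_summary.csv"), row.names = FALSE, quote = FALSE)
  write_phase_map_csv(pm, p("phase_map.csv"))
  utils::write.csv(data.frame(p5_ms = chi$p5, p50_ms = chi$p50,
                              p95_ms = chi$p95, chi = chi$chi),
                   p("chi_summary.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(mean_ari_ms = attr(ari, "mean_ms"),
                              sd_ari_ms = attr(ari, "sd_ms"),
                              n_valid = attr(ari, "n_valid")),
                   p("ari_summary.csv"), row.names = FALSE, quote = FALSE)
  write_cohort_csv(cohort, p("cohort.csv"))
  write_endpoint_report(report, tsv_path = p("endpoint_report.tsv"),
                        json_path = p("endpoint_report.json"))
  utils::write.csv(traj, p("map_trajectory.csv"), row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(config = config_provenance(config), seed = config$seed,
         n_invalid_channels = sum(!amap$valid),
         triangles_rejected = as.list(rej),
         plateau_week = as.list(attr(traj, "plateau_week"))),
    p("provenance.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(recording = recording, activation = amap, repolarization = rmap,
                 ari = ari, conduction = field, phase = pm, chi = chi,
                 cohort = cohort, report = report, trajectory = traj,
                 out_dir = out_dir))
}
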