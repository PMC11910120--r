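#' Load a run configuration from YAML
#'
#' Reads a YAML configuration with optional blocks `chemistry`,
#' `indicator`, `geometry`, `render`, `detection`, `calibration` and
#' top-level `seed`, `times_s`, `d_values`, `label`; missing entries fall
#' back to the package defaults.
#'
#' @param path YAML file path.
#' @return A list of constructed configuration objects (class
#'   `"run_config"`).
#' @export
load_run_config <- function(path) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  build <- function(ctor, block) do.call(ctor, if (is.null(block)) list()
                                         else block)
  ind <- if (is.null(raw$indicator)) bromothymol_blue() else {
    args <- raw$indicator
    args$acid_color <- unlist(args$acid_color)
    args$base_color <- unlist(args$base_color)
    args$ideal_pH_range <- unlist(args$ideal_pH_range)
    do.call(indicator_spec, args)
  }
  cal <- if (is.null(raw$calibration)) calibration_model() else
    calibration_model(
      homography = if (is.null(raw$calibration$homography)) diag(3) else
        matrix(unlist(raw$calibration$homography), 3, 3, byrow = TRUE),
      mm_per_px = if (is.null(raw$calibration$mm_per_px)) 0.0681 else
        raw$calibration$mm_per_px)
  render <- build(render_config, raw$render)
  if (!is.null(raw$seed)) render$seed <- as.integer(raw$seed)
  structure(list(
    chemistry = build(equilibrium_system, raw$chemistry),
    indicator = ind,
    geometry = build(vial_geometry, raw$geometry),
    render = render,
    detection = build(detection_config, raw$detection),
    calibration = cal,
    times_s = if (is.null(raw$times_s)) seq(0, 3600, by = 300) else
      as.numeric(unlist(raw$times_s)),
    d_values = if (is.null(raw$d_values)) rep(11.55e-9, 10) else
      as.numeric(unlist(raw$d_values)),
    label = if (is.null(raw$label)) "hydrogel" else raw$label,
    seed = render$seed), class = "run_config")
}

#' Default run configuration
#'
#' @param ... Overrides for the top-level entries (`d_values`, `times_s`,
#'   `label`, `seed`, or whole configuration objects).
#' @return A `"run_config"` list.
#' @export
default_run_config <- function(...) {
  cfg <- load_run_config(NULL)
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  if (!is.null(dots$seed)) cfg$render$seed <- as.integer(dots$seed)
  cfg
}

#' Simulate a synthetic measurement set
#'
#' Renders the multi-vial series defined by the configuration and writes
#' the PNG frames plus the ground-truth JSON sidecar.
#'
#' @param config A `"run_config"` (see [default_run_config()]).
#' @param out_dir Output directory (created, with a log line, if missing).
#' @return The written directory, invisibly; the series as attribute
#'   `"series"`.
#' @export
run_simulate <- function(config = default_run_config(), out_dir) {
  if (!dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
    message("created output directory ", out_dir)
  }
  series <- render_multivial(config$d_values, config$times_s,
                             config$geometry, config$indicator,
                             config$render)
  write_frame_series(series, out_dir)
  message(sprintf("simulate: wrote %d frames, %d vial(s), seed %d",
                  length(series$frames), length(config$d_values),
                  config$render$seed))
  out <- invisible(out_dir)
  attr(out, "series") <- series
  out
}

#' Detect interfaces in a frame directory
#'
#' Loads a frame series from disk, runs the detection chain for every vial
#' ROI and writes the track CSV.
#'
#' @param frames_dir Directory written by [run_simulate()] /
#'   [write_frame_series()].
#' @param out_csv Output track CSV path.
#' @param rois Optional ROI list overriding the sidecar's.
#' @param cal Optional [calibration_model()]; defaults to identity with
#'   the sidecar's `mm_per_px`.
#' @param config A [detection_config()].
#' @return The track list, invisibly.
#' @export
run_detect <- function(frames_dir, out_csv, rois = NULL, cal = NULL,
                       config = detection_config()) {
  series <- read_frame_series(frames_dir)
  if (is.null(rois)) rois <- series$rois
  if (is.null(rois)) stop("no ROIs available", call. = FALSE)
  if (is.null(cal))
    cal <- calibration_model(mm_per_px = series$meta$mm_per_px)
  tracks <- track_series(series, rois, cal, config)
  write_tracks(tracks, out_csv)
  n_missing <- sum(vapply(tracks, function(t)
    sum(t$flags == "no_interface"), numeric(1)))
  message(sprintf("detect: %d vial(s) x %d frame(s), %d no_interface point(s)",
                  length(tracks), length(series$times_s), n_missing))
  invisible(tracks)
}

#' Analyze interface tracks
#'
#' Fits front kinetics per vial, aggregates replicates, writes the
#' per-time results and summary CSVs, and reports the mean +/- sd.
#'
#' @param tracks_csv Track CSV path (from [run_detect()]), or a list of
#'   `"interface_track"` objects.
#' @param results_csv,summary_csv Output paths (`NULL` to skip).
#' @param label Hydrogel label.
#' @return A list with `fits` (per-vial `"front_fit"`) and `summary`
#'   (`"replicate_summary"`), invisibly.
#' @export
run_analyze <- function(tracks_csv, results_csv = NULL, summary_csv = NULL,
                        label = "hydrogel") {
  tracks <- if (is.character(tracks_csv)) read_tracks(tracks_csv) else
    tracks_csv
  fits <- lapply(tracks, fit_front)
  summ <- summarize_replicates(fits, label)
  write_results(fits, summ, results_csv, summary_csv)
  print(summ)
  invisible(list(fits = fits, summary = summ))
}

#' Run the full simulate - detect - analyze chain
#'
#' @param config A `"run_config"`.
#' @param work_dir Working directory for frames and CSVs (default a
#'   temporary directory).
#' @return The [run_analyze()] result, invisibly.
#' @export
run_end2end <- function(config = default_run_config(),
                        work_dir = tempfile("ida_")) {
  frames <- file.path(work_dir, "frames")
  run_simulate(config, frames)
  tracks_csv <- file.path(work_dir, "tracks.csv")
  run_detect(frames, tracks_csv, cal = config$calibration,
             config = config$detection)
  run_analyze(tracks_csv,
              results_csv = file.path(work_dir, "results.csv"),
              summary_csv = file.path(work_dir, "summary.csv"),
              label = config$label)
}
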