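#' Write a frame series to disk
#'
#' Writes each frame as an 8-bit RGB PNG named `vialset_t{seconds}.png`
#' plus a JSON sidecar (`series.json`) with the acquisition times, ground
#' truth, ROIs, seed and a hash of the generating configuration.
#'
#' @param series A `"frame_series"`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_frame_series <- function(series, dir) {
  stopifnot(inherits(series, "frame_series"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (i in seq_along(series$frames))
    png::writePNG(series$frames[[i]],
                  file.path(dir, sprintf("vialset_t%d.png",
                                         as.integer(series$times_s[i]))))
  side <- list(times_s = series$times_s,
               truth_depth_mm = series$truth_depth_mm,
               clamped = series$clamped,
               D_pseudo = series$D_pseudo,
               seed = series$config$seed,
               config_hash = .config_hash(series$config),
               mm_per_px = series$geometry$mm_per_px,
               gel_top_row = series$geometry$gel_top_row,
               gel_height_mm = series$geometry$gel_height_mm)
  if (!is.null(series$rois))
    side$rois <- lapply(series$rois, function(r)
      r[c("col_start", "col_end", "row_start", "row_end", "gel_top_row")])
  jsonlite::write_json(side, file.path(dir, "series.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

# stable short hash of a configuration list: polynomial rolling hash over
# its serialization, kept below 2^31 so all arithmetic stays exact doubles
.config_hash <- function(cfg) {
  bytes <- as.integer(serialize(unclass(cfg), NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Read a frame series from disk
#'
#' Inverse of [write_frame_series()]: loads the PNG frames (ordered by the
#' sidecar's times) and the sidecar metadata.
#'
#' @param dir Directory written by [write_frame_series()].
#' @return A `"frame_series"`-like list with `frames`, `times_s`, `rois`
#'   (when present) and the sidecar metadata under `meta`.
#' @export
read_frame_series <- function(dir) {
  side_path <- file.path(dir, "series.json")
  if (!file.exists(side_path))
    stop("no series.json sidecar in ", dir, call. = FALSE)
  meta <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  times <- as.numeric(meta$times_s)
  paths <- file.path(dir, sprintf("vialset_t%d.png", as.integer(times)))
  missing <- !file.exists(paths)
  if (any(missing))
    stop("missing frame file(s): ",
         paste(basename(paths[missing]), collapse = ", "), call. = FALSE)
  frames <- lapply(paths, function(p) {
    img <- try(png::readPNG(p), silent = TRUE)
    if (inherits(img, "try-error"))
      stop("corrupt image file: ", basename(p), call. = FALSE)
    img
  })
  rois <- NULL
  if (!is.null(meta$rois))
    rois <- lapply(seq_len(nrow(meta$rois)), function(i)
      do.call(vial_roi, as.list(meta$rois[i, ])))
  structure(list(frames = frames, times_s = times, rois = rois,
                 meta = meta),
            class = "frame_series_on_disk")
}

#' Write interface tracks to CSV
#'
#' One row per (vial, time): `vial_id,time_s,position_px,position_mm,flag`.
#'
#' @param tracks List of `"interface_track"` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  if (inherits(tracks, "interface_track")) tracks <- list(tracks)
  rows <- do.call(rbind, lapply(tracks, function(tr)
    data.frame(vial_id = tr$vial_id, time_s = tr$times_s,
               position_px = tr$position_px,
               position_mm = tr$position_mm, flag = tr$flags)))
  attr_line <- sprintf("# mm_per_px=%.12g x0=%s", tracks[[1]]$mm_per_px,
                       paste(vapply(tracks, function(t)
                         sprintf("%.12g", t$x0_px), character(1)),
                         collapse = ";"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(attr_line, con)
  utils::write.csv(format(rows, digits = 15, trim = TRUE, scientific = FALSE),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read interface tracks from CSV
#'
#' Inverse of [write_tracks()].
#'
#' @param path CSV path written by [write_tracks()].
#' @return List of `"interface_track"` objects.
#' @export
read_tracks <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L)
    stop("track file is empty: ", path, call. = FALSE)
  header <- lines[1]
  if (!startsWith(header, "# mm_per_px="))
    stop("malformed track CSV (missing metadata header), line 1 of ",
         path, call. = FALSE)
  mm_per_px <- as.numeric(sub("^# mm_per_px=([^ ]+).*", "\\1", header))
  x0s <- as.numeric(strsplit(sub(".*x0=", "", header), ";")[[1]])
  df <- tryCatch(
    utils::read.csv(textConnection(lines[-1]), stringsAsFactors = FALSE),
    error = function(e) stop("malformed track CSV: ", conditionMessage(e),
                             call. = FALSE))
  need <- c("vial_id", "time_s", "position_px", "position_mm", "flag")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("malformed track CSV, line 2: missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  ids <- unique(df$vial_id)
  lapply(seq_along(ids), function(i) {
    sub <- df[df$vial_id == ids[i], ]
    structure(list(vial_id = ids[i], times_s = as.numeric(sub$time_s),
                   position_px = as.numeric(sub$position_px),
                   position_mm = as.numeric(sub$position_mm),
                   x0_px = if (i <= length(x0s)) x0s[i] else NA_real_,
                   flags = as.character(sub$flag),
                   mm_per_px = mm_per_px),
              class = "interface_track")
  })
}

#' Write per-time results and replicate summary CSVs
#'
#' @param fits List of `"front_fit"` objects.
#' @param summary A `"replicate_summary"`.
#' @param results_path,summary_path Output CSV paths (either may be `NULL`
#'   to skip).
#' @return Invisibly, a list with the per-time and summary data frames.
#' @export
write_results <- function(fits, summary, results_path = NULL,
                          summary_path = NULL) {
  per_time <- do.call(rbind, lapply(fits, function(f)
    data.frame(hydrogel = summary$label, vial_id = f$vial_id,
               time_s = f$per_time$time_s,
               displacement_mm = f$per_time$displacement_m * 1000,
               Vi_m_per_s = f$per_time$velocity_m_s,
               Dpseudo_m2_per_s = f$per_time$d_pseudo_m2_s)))
  summ <- data.frame(hydrogel = summary$label, n = summary$n,
                     mean_Dpseudo_m2_per_s = summary$mean_D,
                     sd_Dpseudo_m2_per_s = summary$sd_D)
  if (!is.null(results_path))
    utils::write.csv(format(per_time, digits = 15, trim = TRUE),
                     results_path, row.names = FALSE, quote = FALSE)
  if (!is.null(summary_path))
    utils::write.csv(format(summ, digits = 15, trim = TRUE), summary_path,
                     row.names = FALSE, quote = FALSE)
  invisible(list(per_time = per_time, summary = summ))
}
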