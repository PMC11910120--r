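#' Detection configuration
#'
#' Parameters of the interface localization pipeline.
#'
#' @param threshold_method `"otsu"` (default) or `"fixed"`.
#' @param fixed_threshold Threshold in \[0, 1\] when `threshold_method` is
#'   `"fixed"`.
#' @param smooth_window_rows Odd moving-average window applied to the row
#'   profile (1 disables smoothing).
#' @param min_contrast Minimum range of the smoothed row profile for an
#'   interface to be accepted; guards against "detecting" noise in fully
#'   converted or untouched gels.
#' @param crossing_level Profile level whose first downward-scan crossing
#'   defines the interface (default 0.5).
#' @return An object of class `"detection_config"`.
#' @export
detection_config <- function(threshold_method = c("otsu", "fixed"),
                             fixed_threshold = 0.5,
                             smooth_window_rows = 5L, min_contrast = 0.2,
                             crossing_level = 0.5) {
  threshold_method <- match.arg(threshold_method)
  stopifnot(fixed_threshold >= 0, fixed_threshold <= 1,
            smooth_window_rows >= 1,
            smooth_window_rows %% 2 == 1,
            min_contrast >= 0, min_contrast <= 1,
            crossing_level >= 0, crossing_level <= 1)
  structure(list(threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold,
                 smooth_window_rows = as.integer(smooth_window_rows),
                 min_contrast = min_contrast,
                 crossing_level = crossing_level),
            class = "detection_config")
}

#' Vial region of interest
#'
#' Rectangular crop of one vial in a (rectified) frame.  Bounds are 1-based
#' and inclusive; `gel_top_row` is the first row inside the gel, in frame
#' coordinates, and must lie within the row bounds.
#'
#' @param col_start,col_end,row_start,row_end Inclusive pixel bounds.
#' @param gel_top_row First gel row (frame coordinates).
#' @return An object of class `"vial_roi"`.
#' @export
vial_roi <- function(col_start, col_end, row_start, row_end, gel_top_row) {
  stopifnot(col_start >= 1, col_start <= col_end,
            row_start >= 1, row_start <= row_end,
            gel_top_row >= row_start, gel_top_row <= row_end)
  structure(list(col_start = as.integer(col_start),
                 col_end = as.integer(col_end),
                 row_start = as.integer(row_start),
                 row_end = as.integer(row_end),
                 gel_top_row = as.integer(gel_top_row)),
            class = "vial_roi")
}

#' Saturation image
#'
#' HSV saturation of an RGB raster: per pixel `(max - min) / max`, with 0
#' where `max = 0`.  Being a ratio, it is invariant to uniform brightness
#' scaling, which makes the downstream thresholding robust to illumination
#' gradients.
#'
#' @param rgb RGB array (rows x cols x 3) with values in \[0, 1\].
#' @return Matrix of saturations in \[0, 1\].
#' @export
saturation_image <- function(rgb) {
  stopifnot(is.array(rgb), length(dim(rgb)) == 3L, dim(rgb)[3] == 3L)
  mx <- pmax(rgb[, , 1], rgb[, , 2], rgb[, , 3])
  mn <- pmin(rgb[, , 1], rgb[, , 2], rgb[, , 3])
  s <- (mx - mn) / mx
  s[mx == 0] <- 0
  dim(s) <- dim(rgb)[1:2]
  s
}

#' Otsu threshold
#'
#' Maximises the between-class variance over a 256-bin histogram of values
#' in \[0, 1\] using the standard cumulative-moment recursion.  Returns the
#' upper edge of the chosen bin, so "foreground" is `value > threshold`.
#'
#' @param gray Numeric values in \[0, 1\] (any shape).
#' @param levels Number of histogram bins (default 256).
#' @return Threshold in (0, 1), or `NA` when the histogram is degenerate
#'   (constant image: no threshold separates two classes).
#' @export
otsu_threshold <- function(gray, levels = 256L) {
  v <- as.numeric(gray)
  stopifnot(all(is.finite(v)), all(v >= 0), all(v <= 1))
  bins <- pmin(floor(v * levels), levels - 1L)   # bin index 0..levels-1
  h <- tabulate(bins + 1L, nbins = levels)
  if (sum(h > 0) < 2L) return(NA_real_)
  p <- h / sum(h)
  mids <- (seq_len(levels) - 0.5) / levels
  cw <- cumsum(p)
  cm <- cumsum(p * mids)
  mt <- cm[levels]
  t_idx <- seq_len(levels - 1L)
  w0 <- cw[t_idx]; w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sb <- rep(-Inf, levels - 1L)
  sb[valid] <- (mt * w0[valid] - cm[t_idx][valid])^2 /
    (w0[valid] * w1[valid])
  best <- which.max(sb)
  best / levels
}

#' Binarize a grayscale raster
#'
#' Thresholds by Otsu (default) or a fixed level; foreground is strictly
#' above the threshold.  A constant image under Otsu cannot be split: an
#' all-`NA` raster with attribute `no_interface = TRUE` is returned as the
#' no-interface signal (not an error).
#'
#' @param gray Matrix with values in \[0, 1\].
#' @param config A [detection_config()].
#' @return 0/1 matrix with attribute `threshold`; see Details for the
#'   degenerate case.
#' @export
binarize <- function(gray, config = detection_config()) {
  stopifnot(is.matrix(gray), inherits(config, "detection_config"))
  thr <- if (config$threshold_method == "otsu") otsu_threshold(gray)
         else config$fixed_threshold
  if (is.na(thr)) {
    out <- matrix(NA_real_, nrow(gray), ncol(gray))
    attr(out, "no_interface") <- TRUE
    return(out)
  }
  out <- (gray > thr) * 1
  attr(out, "threshold") <- thr
  out
}

#' Row profile of a binarized ROI
#'
#' Per-row mean of the binary values across the ROI columns, smoothed with
#' a truncated moving average of `smooth_window_rows` rows.
#'
#' @param binary Binary matrix in frame coordinates (from [binarize()]).
#' @param roi A [vial_roi()]; must lie within the raster.
#' @param config A [detection_config()].
#' @return Numeric vector, one value per ROI row.
#' @export
row_profile <- function(binary, roi, config = detection_config()) {
  stopifnot(is.matrix(binary), inherits(roi, "vial_roi"))
  if (roi$row_end > nrow(binary) || roi$col_end > ncol(binary))
    stop("ROI exceeds the raster", call. = FALSE)
  sub <- binary[roi$row_start:roi$row_end, roi$col_start:roi$col_end,
                drop = FALSE]
  if (length(sub) == 0) stop("empty ROI", call. = FALSE)
  prof <- rowMeans(sub)
  w <- config$smooth_window_rows
  if (w <= 1L) return(prof)
  half <- (w - 1L) %/% 2L
  n <- length(prof)
  vapply(seq_len(n), function(i) {
    mean(prof[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
}

#' Localize the interface in a row profile
#'
#' Scans downward from the gel surface for the first crossing of
#' `crossing_level` and interpolates linearly between the bracketing rows
#' (pixel-centre coordinates, frame rows).  The profile must span at least
#' `min_contrast`, otherwise no interface is reported.  When several
#' crossings exist the topmost is taken and the multiplicity recorded.
#'
#' @param profile Row profile for the ROI (one value per ROI row).
#' @param roi The matching [vial_roi()].
#' @param config A [detection_config()].
#' @return List with `row` (sub-pixel frame row, `NA` if none), `flag`
#'   (`"ok"`, `"no_interface"` or `"clamped"`), and `n_crossings`.
#' @export
detect_interface <- function(profile, roi, config = detection_config()) {
  stopifnot(inherits(roi, "vial_roi"),
            length(profile) == roi$row_end - roi$row_start + 1L)
  none <- list(row = NA_real_, flag = "no_interface", n_crossings = 0L)
  if (anyNA(profile)) return(none)
  start <- roi$gel_top_row - roi$row_start + 1L
  p <- profile[start:length(profile)]
  if (diff(range(p)) < config$min_contrast) return(none)
  lev <- config$crossing_level
  s <- sign(p - lev)
  cross_at <- which(s[-length(s)] * s[-1] < 0 |
                      (s[-length(s)] != 0 & s[-1] == 0))
  if (length(cross_at) == 0L) return(none)
  i <- cross_at[1L]
  frac <- (p[i] - lev) / (p[i] - p[i + 1L])
  row_abs <- (roi$gel_top_row + i - 1L) + frac
  # crossings within one smoothing window of the gel bottom are
  # truncation-biased: both the moving-average window and the colour
  # transition itself are cut off by the vial floor, so the localization is
  # no longer trustworthy and the point is flagged rather than reported ok
  margin <- max(3L, config$smooth_window_rows)
  flag <- if (i >= length(p) - margin) "clamped" else "ok"
  list(row = row_abs, flag = flag, n_crossings = length(cross_at))
}

#' Track the interface through a frame series
#'
#' Full detection chain per frame and vial: rectification, ROI crop,
#' saturation extraction, binarization, row profile, sub-pixel crossing.
#' Frame 1 (time 0) is the pre-gassing reference: the reference position
#' `x0` per vial is the detected interface if one is visible, otherwise
#' the gel surface (the top edge of `gel_top_row`).  Depths are
#' `(position_px - x0) * mm_per_px`, positive downward.
#'
#' @param series A `"frame_series"` (or any list with `frames` and
#'   `times_s`).
#' @param rois List of [vial_roi()] (defaults to `series$rois` when
#'   present).
#' @param cal A [calibration_model()].
#' @param config A [detection_config()].
#' @return List of `"interface_track"` objects, one per vial, each with
#'   `vial_id`, `times_s`, `position_px`, `position_mm`, `x0_px`, `flags`,
#'   `mm_per_px`.
#' @export
track_series <- function(series, rois = NULL, cal = calibration_model(),
                         config = detection_config()) {
  if (is.null(rois)) rois <- series$rois
  if (is.null(rois)) stop("no ROIs supplied and none in the series",
                          call. = FALSE)
  if (inherits(rois, "vial_roi")) rois <- list(rois)
  stopifnot(length(series$frames) == length(series$times_s))
  n_f <- length(series$frames)
  n_v <- length(rois)
  pos <- matrix(NA_real_, n_f, n_v)
  flags <- matrix("no_interface", n_f, n_v)
  for (f in seq_len(n_f)) {
    frame <- rectify(series$frames[[f]], cal)
    sat <- saturation_image(frame)
    for (v in seq_len(n_v)) {
      roi <- rois[[v]]
      crop <- sat[roi$row_start:roi$row_end, roi$col_start:roi$col_end,
                  drop = FALSE]
      bin <- binarize(crop, config)
      # crop is already the ROI; profile in ROI-local coordinates
      local_roi <- vial_roi(1L, ncol(crop), 1L, nrow(crop),
                            roi$gel_top_row - roi$row_start + 1L)
      prof <- row_profile(bin, local_roi, config)
      det <- detect_interface(prof, local_roi, config)
      if (!is.na(det$row))
        pos[f, v] <- det$row + roi$row_start - 1L
      flags[f, v] <- det$flag
    }
  }
  lapply(seq_len(n_v), function(v) {
    x0 <- if (flags[1, v] == "ok") pos[1, v] else rois[[v]]$gel_top_row - 0.5
    mm <- (pos[, v] - x0) * cal$mm_per_px
    structure(list(vial_id = v, times_s = series$times_s,
                   position_px = pos[, v], position_mm = mm,
                   x0_px = x0, flags = flags[, v],
                   mm_per_px = cal$mm_per_px),
              class = "interface_track")
  })
}

#' @export
print.interface_track <- function(x, ...) {
  cat(sprintf("Interface track, vial %s: %d frames, x0 = %.2f px\n",
              x$vial_id, length(x$times_s), x$x0_px))
  print(data.frame(time_s = x$times_s,
                   position_mm = round(x$position_mm, 3),
                   flag = x$flags), row.names = FALSE)
  invisible(x)
}
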