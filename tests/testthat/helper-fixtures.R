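# Shared fixtures and independent oracles used across the suite.

# Default single-vial ROI covering exactly the gel column of a geometry.
gel_roi <- function(g = vial_geometry()) {
  vial_roi(1, g$width_px, g$gel_top_row,
           g$gel_top_row + g$gel_rows - 1L, g$gel_top_row)
}

# Run the detection chain on one in-memory frame; returns depth in mm
# below the gel surface (NA when no interface is reported).
detect_depth_mm <- function(img, g = vial_geometry(),
                            config = detection_config()) {
  roi <- gel_roi(g)
  sat <- saturation_image(img)
  crop <- sat[roi$row_start:roi$row_end, roi$col_start:roi$col_end,
              drop = FALSE]
  lroi <- vial_roi(1, ncol(crop), 1, nrow(crop), 1)
  det <- detect_interface(row_profile(binarize(crop, config), lroi, config),
                          lroi, config)
  if (is.na(det$row) || det$flag != "ok") return(NA_real_)
  (det$row - 0.5) * g$mm_per_px
}

# Brute-force Otsu oracle: explicit two-class between-class variance,
# maximized by looping over every one of the 256 cut points.
otsu_brute_force <- function(gray, levels = 256L) {
  v <- as.numeric(gray)
  bins <- pmin(floor(v * levels), levels - 1L)
  best_var <- -Inf
  best_t <- NA_real_
  for (t in 0:(levels - 2L)) {
    lo <- bins <= t
    n0 <- sum(lo); n1 <- sum(!lo)
    if (n0 == 0 || n1 == 0) next
    mids <- (bins + 0.5) / levels
    m0 <- mean(mids[lo]); m1 <- mean(mids[!lo])
    w0 <- n0 / length(bins); w1 <- n1 / length(bins)
    bv <- w0 * w1 * (m0 - m1)^2
    if (bv > best_var) { best_var <- bv; best_t <- (t + 1) / levels }
  }
  best_t
}

# Synthetic interface track following the sqrt-t law exactly (positions mm).
exact_track <- function(D, times = seq(300, 1200, by = 300), vial_id = 1) {
  list(vial_id = vial_id, times_s = c(0, times),
       position_mm = c(0, front_position(times, D) * 1000),
       flags = rep("ok", length(times) + 1L))
}
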