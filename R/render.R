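#' Vial geometry
#'
#' Pixel-space geometry of one rendered vial: image size, the row at which
#' the gel surface sits, the gel height in mm, the pixel scale, and the
#' height of the supernatant water band above the gel.  Defaults model a
#' 6 mm inner-diameter vial holding 150 uL of gel (a 5.3 mm column) imaged
#' at 0.0681 mm/px.
#'
#' Rows are 1-based, row 1 at the image top; depth increases downward.
#'
#' @param width_px,height_px Image size in pixels.
#' @param gel_top_row First image row inside the gel (1-based).
#' @param gel_height_mm Gel column height, mm.
#' @param mm_per_px Pixel scale, mm per pixel.
#' @param water_rows Height of the water band directly above the gel, rows.
#' @return An object of class `"vial_geometry"`.
#' @export
vial_geometry <- function(width_px = 88L, height_px = 112L,
                          gel_top_row = 25L, gel_height_mm = 5.3,
                          mm_per_px = 0.0681, water_rows = 18L) {
  stopifnot(width_px >= 1, height_px >= 1, gel_top_row >= 1,
            gel_height_mm > 0, mm_per_px > 0, water_rows >= 0)
  gel_rows <- floor(gel_height_mm / mm_per_px)
  if (gel_top_row + gel_rows - 1 > height_px)
    stop("gel column does not fit below gel_top_row within height_px",
         call. = FALSE)
  if (water_rows >= gel_top_row)
    stop("water band extends above the image top", call. = FALSE)
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 gel_top_row = as.integer(gel_top_row),
                 gel_height_mm = gel_height_mm,
                 mm_per_px = mm_per_px,
                 water_rows = as.integer(water_rows),
                 gel_rows = as.integer(gel_rows)),
            class = "vial_geometry")
}

#' Rendering configuration
#'
#' Optical parameters of the synthetic vial renderer.
#'
#' `transition_width_mm` is the 10--90% width of the logistic colour
#' transition at the front (the logistic scale is `width / (2 ln 9)`).
#' `yellow_filter_strength` models the yellow backlight filter foil that
#' merges the acidified gel and the green transition colour with the
#' background; the default 0.75 places the saturation of the 50/50 mixed
#' colour midway between the pure-phase saturations, so the thresholding
#' detector localizes the true front midpoint without bias.
#'
#' @param transition_width_mm 10--90% width of the front colour gradient, mm.
#' @param noise_sd Additive Gaussian sensor noise, per channel, as a
#'   fraction of full scale (clipped to \[0, 1\] after addition).
#' @param illum_gradient Fractional top-to-bottom brightness drop in \[0, 1).
#' @param yellow_filter_strength Blue-channel attenuation in \[0, 1\].
#' @param meniscus_drop_mm_per_h Evaporation rate of the water meniscus.
#' @param seed Integer seed controlling all renderer randomness.
#' @return An object of class `"render_config"`.
#' @export
render_config <- function(transition_width_mm = 0.4, noise_sd = 0.02,
                          illum_gradient = 0.1,
                          yellow_filter_strength = 0.75,
                          meniscus_drop_mm_per_h = 0.3, seed = 1L) {
  stopifnot(transition_width_mm > 0, noise_sd >= 0,
            illum_gradient >= 0, illum_gradient < 1,
            yellow_filter_strength >= 0, yellow_filter_strength <= 1,
            meniscus_drop_mm_per_h >= 0,
            is.numeric(seed), length(seed) == 1L)
  structure(list(transition_width_mm = transition_width_mm,
                 noise_sd = noise_sd, illum_gradient = illum_gradient,
                 yellow_filter_strength = yellow_filter_strength,
                 meniscus_drop_mm_per_h = meniscus_drop_mm_per_h,
                 seed = as.integer(seed)),
            class = "render_config")
}

# background (yellow backlight through empty vial) and water colours
.bg_color <- c(0.96, 0.93, 0.60)
.water_color <- c(0.88, 0.90, 0.93)
.meniscus_color <- c(0.35, 0.35, 0.35)

#' Apply the yellow backlight filter
#'
#' Emulates a yellow filter foil on the light table: attenuates the blue
#' channel by `1 - strength` and leaves red and green untouched.
#'
#' @param image RGB array (rows x cols x 3) in \[0, 1\].
#' @param strength Attenuation in \[0, 1\]; 0 is the identity.
#' @return Filtered RGB array.
#' @export
apply_yellow_filter <- function(image, strength) {
  stopifnot(is.array(image), length(dim(image)) == 3L, dim(image)[3] == 3L,
            strength >= 0, strength <= 1)
  image[, , 3] <- image[, , 3] * (1 - strength)
  image
}

#' Render one synthetic vial frame
#'
#' Draws a backlit vial: background, water band with meniscus, and a gel
#' column whose colour blends from the indicator's acid colour (above the
#' front) to its base colour (below) through a logistic transition centred
#' at `front_depth_mm` below the gel surface.  An illumination gradient,
#' the yellow filter and seeded sensor noise are applied, in that order.
#'
#' @param front_depth_mm True front depth below the gel surface, mm.
#'   Values outside \[0, gel height\] are clamped; the returned array then
#'   carries attribute `clamped = TRUE`.
#' @param geometry A [vial_geometry()].
#' @param indicator An [indicator_spec()].
#' @param config A [render_config()].
#' @param time_s Acquisition time, s (drives the meniscus drop).
#' @param frame_index Frame number, mixed into the noise seed so frames of
#'   a series get independent noise while remaining reproducible.
#' @return RGB array (height x width x 3) in \[0, 1\].
#' @export
render_frame <- function(front_depth_mm, geometry = vial_geometry(),
                         indicator = bromothymol_blue(),
                         config = render_config(), time_s = 0,
                         frame_index = 0L) {
  stopifnot(inherits(geometry, "vial_geometry"),
            inherits(indicator, "indicator_spec"),
            inherits(config, "render_config"))
  clamped <- FALSE
  if (front_depth_mm < 0 || front_depth_mm > geometry$gel_height_mm) {
    front_depth_mm <- min(max(front_depth_mm, 0), geometry$gel_height_mm)
    clamped <- TRUE
  }
  h <- geometry$height_px; w <- geometry$width_px
  img <- array(rep(.bg_color, each = h * w), dim = c(h, w, 3))

  # water band: from the (dropping) meniscus down to the gel surface
  drop_px <- config$meniscus_drop_mm_per_h * (time_s / 3600) /
    geometry$mm_per_px
  men_row <- min(geometry$gel_top_row - 1L,
                 max(1L, as.integer(round(
                   geometry$gel_top_row - geometry$water_rows + drop_px))))
  if (men_row < geometry$gel_top_row - 1L) {
    wat <- (men_row + 1L):(geometry$gel_top_row - 1L)
    img[wat, , ] <- rep(.water_color, each = length(wat) * w)
  }
  img[men_row, , ] <- rep(.meniscus_color, each = w)

  # gel column: logistic acid/base blend, row centres at (j - 0.5) px depth.
  # An untouched column (front at 0, e.g. the pre-gassing reference) is pure
  # base; a fully converted one (front at/past the gel bottom) pure acid.
  k <- config$transition_width_mm / (2 * log(9))
  gel <- geometry$gel_top_row:(geometry$gel_top_row + geometry$gel_rows - 1L)
  depth <- (seq_along(gel) - 0.5) * geometry$mm_per_px
  w_acid <- if (front_depth_mm <= 0) rep(0, length(depth))
            else if (front_depth_mm >= geometry$gel_height_mm)
              rep(1, length(depth))
            else 1 / (1 + exp((depth - front_depth_mm) / k))
  for (ch in 1:3)
    img[gel, , ch] <- w_acid * indicator$acid_color[ch] +
      (1 - w_acid) * indicator$base_color[ch]

  # illumination gradient (multiplicative, top bright)
  if (config$illum_gradient > 0) {
    g <- 1 - config$illum_gradient * (seq_len(h) - 1) / (h - 1)
    img <- img * array(g, dim = c(h, w, 3))
  }
  img <- apply_yellow_filter(img, config$yellow_filter_strength)

  if (config$noise_sd > 0) {
    old <- .save_rng()
    on.exit(.restore_rng(old), add = TRUE)
    set.seed((config$seed + 7919L * (as.integer(frame_index) %% 100000L)) %%
               .Machine$integer.max)
    img <- img + array(stats::rnorm(h * w * 3, 0, config$noise_sd),
                       dim = c(h, w, 3))
    img[img < 0] <- 0
    img[img > 1] <- 1
  }
  if (clamped) attr(img, "clamped") <- TRUE
  img
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Render a time-lapse series for one vial
#'
#' Renders frames at the given times with the front at
#' `front_position(t, D_pseudo)` and records the true depth per frame.
#' The first time must be 0: it is the pre-gassing reference frame from
#' which the detector fixes the reference position.
#'
#' @param times_s Strictly increasing acquisition times, s, starting at 0.
#' @param D_pseudo Ground-truth pseudo diffusion coefficient, m^2/s.
#' @param geometry,indicator,config See [render_frame()].
#' @return An object of class `"frame_series"`: list with `frames` (list of
#'   RGB arrays), `times_s`, `truth_depth_mm`, `clamped` (logical per
#'   frame), and the generating `geometry`, `indicator`, `config`.
#' @export
render_series <- function(times_s, D_pseudo, geometry = vial_geometry(),
                          indicator = bromothymol_blue(),
                          config = render_config()) {
  stopifnot(is.numeric(times_s), length(times_s) >= 1,
            all(diff(times_s) > 0))
  if (times_s[1] != 0)
    stop("times_s must start at 0 (the pre-gassing reference frame)",
         call. = FALSE)
  depth_mm <- front_position(times_s, D_pseudo) * 1000
  clamped <- depth_mm > geometry$gel_height_mm
  frames <- lapply(seq_along(times_s), function(i)
    render_frame(depth_mm[i], geometry, indicator, config,
                 time_s = times_s[i], frame_index = i - 1L))
  structure(list(frames = frames, times_s = times_s,
                 truth_depth_mm = pmin(depth_mm, geometry$gel_height_mm),
                 clamped = clamped, D_pseudo = D_pseudo,
                 geometry = geometry, indicator = indicator,
                 config = config),
            class = "frame_series")
}

#' Render a multi-vial composite series
#'
#' Lays up to ten vials side by side in each frame, with independent noise
#' streams per vial, and returns the composite series together with the
#' region of interest of every vial for the detection stage.
#'
#' @param d_values Numeric vector of per-vial ground-truth `D_pseudo`
#'   (m^2/s), one per vial, at most 10.
#' @param times_s Acquisition times, s, starting at 0.
#' @param geometry Shared [vial_geometry()] for all vials.
#' @param indicator,config See [render_frame()].
#' @param gap_px Blank background columns between adjacent vials.
#' @return A `"frame_series"` whose frames are composites, with extra
#'   elements `rois` (list of [vial_roi()]) and `truth_depth_mm` a matrix
#'   (frames x vials); `clamped` is likewise a matrix.
#' @export
render_multivial <- function(d_values, times_s = seq(0, 3600, by = 300),
                             geometry = vial_geometry(),
                             indicator = bromothymol_blue(),
                             config = render_config(), gap_px = 6L) {
  n_vial <- length(d_values)
  stopifnot(n_vial >= 1, n_vial <= 10, gap_px >= 0)
  series <- lapply(seq_len(n_vial), function(v) {
    cfg <- config
    cfg$seed <- (config$seed + 104729L * v) %% .Machine$integer.max
    render_series(times_s, d_values[v], geometry, indicator, cfg)
  })
  w <- geometry$width_px; h <- geometry$height_px
  stride <- w + gap_px
  total_w <- n_vial * w + (n_vial - 1L) * gap_px
  rois <- lapply(seq_len(n_vial), function(v) {
    c0 <- (v - 1L) * stride + 1L
    vial_roi(col_start = c0, col_end = c0 + w - 1L,
             row_start = geometry$gel_top_row,
             row_end = geometry$gel_top_row + geometry$gel_rows - 1L,
             gel_top_row = geometry$gel_top_row)
  })
  frames <- lapply(seq_along(times_s), function(i) {
    comp <- array(rep(.bg_color * (1 - config$yellow_filter_strength *
                                     c(0, 0, 1)),
                      each = h * total_w),
                  dim = c(h, total_w, 3))
    for (v in seq_len(n_vial)) {
      cols <- ((v - 1L) * stride + 1L):((v - 1L) * stride + w)
      comp[, cols, ] <- series[[v]]$frames[[i]]
    }
    comp
  })
  truth <- vapply(series, function(s) s$truth_depth_mm,
                  numeric(length(times_s)))
  clamp <- vapply(series, function(s) s$clamped, logical(length(times_s)))
  structure(list(frames = frames, times_s = times_s,
                 truth_depth_mm = truth, clamped = clamp,
                 D_pseudo = d_values, rois = rois, geometry = geometry,
                 indicator = indicator, config = config),
            class = "frame_series")
}

#' @export
print.frame_series <- function(x, ...) {
  n_vial <- if (is.matrix(x$truth_depth_mm)) ncol(x$truth_depth_mm) else 1L
  cat(sprintf("Synthetic frame series: %d frame(s), %d vial(s), %d x %d px\n",
              length(x$frames), n_vial,
              dim(x$frames[[1]])[1], dim(x$frames[[1]])[2]))
  cat(sprintf("  times %g..%g s, seed %d\n", min(x$times_s), max(x$times_s),
              x$config$seed))
  invisible(x)
}
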