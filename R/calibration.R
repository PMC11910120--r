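#' Calibration model
#'
#' Geometric rectification (a 3x3 homography mapping output pixel
#' coordinates to input coordinates' frame) plus the pixel scale.  The
#' default is the identity homography with the 0.0681 mm/px conversion
#' factor (6.81 mm displayed with 100 pixels).
#'
#' @param homography Invertible 3x3 matrix; identity means no warp.
#' @param mm_per_px Pixel scale, mm per pixel, `> 0`.
#' @return An object of class `"calibration_model"`.
#' @export
calibration_model <- function(homography = diag(3), mm_per_px = 0.0681) {
  stopifnot(is.matrix(homography), all(dim(homography) == c(3, 3)),
            is.numeric(mm_per_px), mm_per_px > 0)
  if (abs(det(homography)) < 1e-12)
    stop("homography is singular", call. = FALSE)
  structure(list(homography = homography, mm_per_px = mm_per_px),
            class = "calibration_model")
}

#' Estimate a homography from four point pairs
#'
#' Direct linear transform from exactly four source/destination point
#' correspondences (e.g. vial-holder fiducials), for building a
#' [calibration_model()] without a full camera calibration.
#'
#' @param src,dst 4x2 matrices of (x, y) coordinates; `dst = H %*% src` in
#'   homogeneous coordinates.
#' @return A 3x3 homography matrix normalised to `H[3,3] = 1`.
#' @export
homography_from_points <- function(src, dst) {
  stopifnot(is.matrix(src), is.matrix(dst), all(dim(src) == c(4, 2)),
            all(dim(dst) == c(4, 2)))
  A <- matrix(0, 8, 8); b <- numeric(8)
  for (i in 1:4) {
    x <- src[i, 1]; y <- src[i, 2]; u <- dst[i, 1]; v <- dst[i, 2]
    A[2 * i - 1, ] <- c(x, y, 1, 0, 0, 0, -u * x, -u * y)
    A[2 * i, ]     <- c(0, 0, 0, x, y, 1, -v * x, -v * y)
    b[2 * i - 1] <- u; b[2 * i] <- v
  }
  h <- solve(A, b)
  matrix(c(h, 1), 3, 3, byrow = TRUE)
}

#' Rectify an image
#'
#' Warps the image with the inverse of the calibration homography using
#' bilinear sampling onto a same-size canvas (coordinates are (x = column,
#' y = row), 1-based pixel centres).  The identity homography returns the
#' input unchanged.  Samples falling outside the source are filled with 0.
#'
#' @param image RGB array (rows x cols x 3) or a matrix.
#' @param cal A [calibration_model()].
#' @return Rectified array of the same dimensions.
#' @export
rectify <- function(image, cal) {
  stopifnot(inherits(cal, "calibration_model"))
  H <- cal$homography
  if (isTRUE(all.equal(H / H[3, 3], diag(3), tolerance = 1e-12)))
    return(image)
  d <- dim(image)
  nr <- d[1]; nc <- d[2]
  grid <- cbind(rep(seq_len(nc), each = nr),      # x (col)
                rep(seq_len(nr), times = nc), 1)  # y (row)
  srch <- grid %*% t(solve(H))
  sx <- srch[, 1] / srch[, 3]
  sy <- srch[, 2] / srch[, 3]
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  sample_plane <- function(plane) {
    gv <- function(yy, xx) {
      ok <- yy >= 1 & yy <= nr & xx >= 1 & xx <= nc
      out <- numeric(length(yy))
      out[ok] <- plane[cbind(yy[ok], xx[ok])]
      out
    }
    v <- gv(y0, x0) * (1 - fx) * (1 - fy) +
      gv(y0, x0 + 1) * fx * (1 - fy) +
      gv(y0 + 1, x0) * (1 - fx) * fy +
      gv(y0 + 1, x0 + 1) * fx * fy
    matrix(v, nr, nc)
  }
  if (length(d) == 3L) {
    out <- array(0, dim = d)
    for (ch in seq_len(d[3])) out[, , ch] <- sample_plane(image[, , ch])
    out
  } else sample_plane(image)
}

#' Convert pixels to millimetres
#'
#' @param px Pixel value(s).
#' @param cal A [calibration_model()].
#' @return `px * mm_per_px`.
#' @export
px_to_mm <- function(px, cal = calibration_model()) {
  stopifnot(is.numeric(px), all(is.finite(px)))
  px * cal$mm_per_px
}

#' Convert millimetres to pixels
#'
#' @param mm Millimetre value(s).
#' @param cal A [calibration_model()].
#' @return `mm / mm_per_px`.
#' @export
mm_to_px <- function(mm, cal = calibration_model()) {
  stopifnot(is.numeric(mm), all(is.finite(mm)))
  mm / cal$mm_per_px
}
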