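#' Interface velocity
#'
#' Mean velocity of the dye front over `(0, t]`: `|x0 - xt| / t`.
#' Displacement is taken as a magnitude, with downward motion positive by
#' the tracking convention.
#'
#' @param x0 Reference interface position, m.
#' @param xt Interface position at time `t`, m.
#' @param t Elapsed time, s, `> 0`.  Vectorised over `xt`/`t`.
#' @return Velocity, m/s.
#' @export
interface_velocity <- function(x0, xt, t) {
  if (any(!is.finite(t)) || any(t <= 0))
    stop("t must be finite and > 0", call. = FALSE)
  abs(x0 - xt) / t
}

#' Pseudo diffusion coefficient
#'
#' Effective diffusion proxy of the moving front: `(x0 - xt)^2 / (2 t)`.
#' "Pseudo" because it is a threshold-dependent front-motion coefficient,
#' not an absolute effective diffusivity.
#'
#' @inheritParams interface_velocity
#' @return Pseudo diffusion coefficient, m^2/s.
#' @examples
#' pseudo_diffusion(0, 6.448e-3, 1800)   # ~11.55e-9
#' @export
pseudo_diffusion <- function(x0, xt, t) {
  if (any(!is.finite(t)) || any(t <= 0))
    stop("t must be finite and > 0", call. = FALSE)
  (x0 - xt)^2 / (2 * t)
}

#' Gravimetric porosity
#'
#' Void fraction of a gel estimated from wet and dry weights:
#' `(wet - dry) / wet`.
#'
#' @param wet_weight Weight of the wet hydrogel, g, `> 0`.
#' @param dry_weight Weight of the dry bulk material, g, with
#'   `0 < dry_weight <= wet_weight`.
#' @return Porosity in \[0, 1).
#' @examples
#' porosity(1.000, 0.042)   # 0.958
#' @export
porosity <- function(wet_weight, dry_weight) {
  stopifnot(is.numeric(wet_weight), is.numeric(dry_weight))
  if (any(wet_weight <= 0) || any(dry_weight <= 0))
    stop("weights must be > 0", call. = FALSE)
  if (any(dry_weight > wet_weight))
    stop("dry_weight must not exceed wet_weight", call. = FALSE)
  (wet_weight - dry_weight) / wet_weight
}

#' Fit front kinetics to an interface track
#'
#' The central model fit: for every usable (`"ok"`, `t > 0`) point of a
#' track it computes the interface velocity and the per-time pseudo
#' diffusion coefficient, and it fits the square-root-of-time law
#' `displacement^2 = 2 D t` by least squares through the origin
#' (`D_hat = sum(d_i^2 t_i) / (2 sum(t_i^2))`).  Two summaries of `D` are
#' kept: `replicate_mean_D`, the mean of the per-time coefficients (the
#' per-vial value entering replicate summaries), and `fitted_D` from the
#' regression.
#'
#' @param track An `"interface_track"` from [track_series()], or any list
#'   with `times_s`, `position_mm`, `flags`, `vial_id`.
#' @return An object of class `"front_fit"` with elements `per_time`
#'   (data frame: `time_s`, `displacement_m`, `velocity_m_s`,
#'   `d_pseudo_m2_s`), `replicate_mean_D`, `fitted_D`, `vial_id`, `n_used`.
#' @seealso [summarize_replicates()], [fold_ratio()]
#' @export
fit_front <- function(track) {
  stopifnot(!is.null(track$times_s), !is.null(track$position_mm))
  flags <- if (is.null(track$flags)) rep("ok", length(track$times_s))
           else track$flags
  use <- flags == "ok" & track$times_s > 0 & !is.na(track$position_mm)
  if (sum(use) < 2L)
    stop("need >= 2 usable points after t = 0; flags were: ",
         paste(flags, collapse = ", "), call. = FALSE)
  t <- track$times_s[use]
  d <- abs(track$position_mm[use]) / 1000    # m
  per_time <- data.frame(time_s = t, displacement_m = d,
                         velocity_m_s = interface_velocity(0, d, t),
                         d_pseudo_m2_s = pseudo_diffusion(0, d, t))
  fitted_D <- sum(d^2 * t) / (2 * sum(t^2))
  structure(list(per_time = per_time,
                 replicate_mean_D = mean(per_time$d_pseudo_m2_s),
                 fitted_D = fitted_D,
                 vial_id = if (is.null(track$vial_id)) NA else track$vial_id,
                 n_used = sum(use), n_total = sum(track$times_s > 0),
                 track = track),
            class = "front_fit")
}

#' @export
print.front_fit <- function(x, ...) {
  cat(sprintf("Front kinetics fit (vial %s): %d/%d usable points\n",
              x$vial_id, x$n_used, x$n_total))
  cat(sprintf("  mean per-time D_pseudo: %.3g m^2/s\n", x$replicate_mean_D))
  cat(sprintf("  fitted D (d^2 = 2 D t): %.3g m^2/s\n", x$fitted_D))
  invisible(x)
}

#' @export
summary.front_fit <- function(object, ...) {
  res <- stats::residuals(object)
  out <- list(fit = object,
              resid_sd_m = stats::sd(res),
              d_range = range(object$per_time$d_pseudo_m2_s))
  class(out) <- "summary.front_fit"
  out
}

#' @export
print.summary.front_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  per-time D_pseudo range: %.3g .. %.3g m^2/s\n",
              x$d_range[1], x$d_range[2]))
  cat(sprintf("  residual sd of displacement: %.3g m\n", x$resid_sd_m))
  print(x$fit$per_time, row.names = FALSE)
  invisible(x)
}

#' @export
coef.front_fit <- function(object, ...) {
  c(fitted_D = object$fitted_D, mean_D = object$replicate_mean_D)
}

#' @export
predict.front_fit <- function(object, newtimes = NULL, ...) {
  if (is.null(newtimes)) newtimes <- object$per_time$time_s
  front_position(newtimes, object$fitted_D)
}

#' @export
residuals.front_fit <- function(object, ...) {
  object$per_time$displacement_m -
    front_position(object$per_time$time_s, object$fitted_D)
}

#' @export
plot.front_fit <- function(x, ...) {
  t <- x$per_time$time_s
  graphics::plot(sqrt(t), x$per_time$displacement_m * 1000,
                 xlab = expression(sqrt(t) ~ "(" * s^{1/2} * ")"),
                 ylab = "displacement (mm)",
                 main = sprintf("Front displacement, vial %s", x$vial_id),
                 ...)
  tt <- seq(0, max(t), length.out = 100)
  graphics::lines(sqrt(tt), front_position(tt, x$fitted_D) * 1000)
  invisible(x)
}

#' @export
simulate.front_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  t <- object$per_time$time_s
  mu <- front_position(t, object$fitted_D)
  sdr <- stats::sd(stats::residuals(object))
  as.data.frame(replicate(nsim, pmax(0, mu + stats::rnorm(length(t), 0, sdr))))
}

#' Summarize replicate vials
#'
#' Mean and sample standard deviation (n - 1 denominator) of the per-vial
#' mean pseudo diffusion coefficients across replicates.
#'
#' @param fits List of `"front_fit"` objects (one per vial).
#' @param label Hydrogel label for reporting.
#' @return An object of class `"replicate_summary"` with `n`, `mean_D`,
#'   `sd_D`, `label`.
#' @export
summarize_replicates <- function(fits, label = "hydrogel") {
  if (inherits(fits, "front_fit")) fits <- list(fits)
  if (length(fits) == 0) stop("no fits supplied", call. = FALSE)
  stopifnot(all(vapply(fits, inherits, logical(1), "front_fit")))
  d <- vapply(fits, function(f) f$replicate_mean_D, numeric(1))
  structure(list(n = length(d), mean_D = mean(d),
                 sd_D = if (length(d) > 1) stats::sd(d) else 0,
                 per_vial_D = d, label = label),
            class = "replicate_summary")
}

#' @export
print.replicate_summary <- function(x, ...) {
  cat(sprintf("%s: D_pseudo = %.3g +/- %.3g m^2/s (mean +/- sd, n = %d)\n",
              x$label, x$mean_D, x$sd_D, x$n))
  invisible(x)
}

#' Fold ratio between two hydrogels
#'
#' Ratio of mean pseudo diffusion coefficients, `a / b`.
#'
#' @param a,b `"replicate_summary"` objects.
#' @return Unitless ratio.
#' @export
fold_ratio <- function(a, b) {
  stopifnot(inherits(a, "replicate_summary"),
            inherits(b, "replicate_summary"))
  if (b$mean_D <= 0) stop("denominator mean_D must be > 0", call. = FALSE)
  a$mean_D / b$mean_D
}
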