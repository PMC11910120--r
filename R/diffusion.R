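#' Dye-front depth under the square-root-of-time law
#'
#' Inverts the pseudo diffusion relation `D = d^2 / (2 t)`: a front with
#' constant pseudo diffusion coefficient `D_pseudo` sits at depth
#' `sqrt(2 * D_pseudo * t)` at time `t`.
#'
#' @param t Time(s) since gassing started, s, `>= 0`.  Vectorised.
#' @param D_pseudo Pseudo diffusion coefficient, m^2/s, `> 0`.
#' @return Depth(s) below the reference surface, m.
#' @examples
#' front_position(1800, 11.55e-9)   # ~6.45 mm
#' @export
front_position <- function(t, D_pseudo) {
  stopifnot(is.numeric(t), is.numeric(D_pseudo), length(D_pseudo) == 1L,
            D_pseudo > 0)
  if (any(!is.finite(t)) || any(t < 0))
    stop("t must be finite and >= 0", call. = FALSE)
  sqrt(2 * D_pseudo * t)
}

#' 1-D diffusion field
#'
#' Grid and parameters for a one-dimensional diffusion problem with a
#' constant-concentration boundary at the top (x = 0) and a zero-flux
#' bottom, used as a physics-grounded generator for front motion.
#'
#' @param D Diffusion coefficient, m^2/s, `> 0`.
#' @param c0 Boundary concentration at x = 0, mol/L, `>= 0`.
#' @param length Domain depth, m.
#' @param n_nodes Number of grid nodes (including both boundaries).
#' @param dt Time step, s.  Must satisfy the explicit stability bound
#'   `dt <= dx^2 / (2 D)`; [diffuse_1d()] enforces it.
#' @return An object of class `"diffusion_field"`.
#' @export
diffusion_field <- function(D, c0, length, n_nodes, dt) {
  stopifnot(is.numeric(D), D > 0, is.numeric(c0), c0 >= 0,
            is.numeric(length), length > 0,
            is.numeric(n_nodes), n_nodes >= 3, n_nodes == round(n_nodes),
            is.numeric(dt), dt > 0)
  structure(list(D = D, c0 = c0, length = length,
                 n_nodes = as.integer(n_nodes), dt = dt,
                 dx = length / (n_nodes - 1)),
            class = "diffusion_field")
}

#' Semi-infinite constant-boundary concentration profile
#'
#' Closed-form solution of 1-D diffusion into a semi-infinite medium with a
#' constant boundary concentration: `c(x, t) = c0 * erfc(x / (2 sqrt(D t)))`.
#'
#' @param x Depth(s), m, `>= 0`.  Vectorised.
#' @param t Time, s, `> 0`.
#' @param field A [diffusion_field()] (its `D` and `c0` are used).
#' @return Concentration(s), mol/L.
#' @export
concentration_profile <- function(x, t, field) {
  stopifnot(inherits(field, "diffusion_field"), is.numeric(x),
            is.numeric(t), length(t) == 1L)
  if (any(x < 0)) stop("x must be >= 0", call. = FALSE)
  if (!is.finite(t) || t <= 0) stop("t must be > 0", call. = FALSE)
  field$c0 * .erfc(x / (2 * sqrt(field$D * t)))
}

# complementary error function via the normal CDF (exact identity)
.erfc <- function(x) 2 * stats::pnorm(-sqrt(2) * x)

#' Explicit finite-difference 1-D diffusion
#'
#' Integrates the diffusion equation on the field's grid with forward-time
#' centred-space stepping: the top node is held at `c0`, the bottom node is
#' zero-flux.  The explicit scheme requires `dt <= dx^2 / (2 D)`; a
#' violating configuration is rejected with the maximal admissible `dt`
#' named in the error.
#'
#' @param field A [diffusion_field()].
#' @param t_end End time, s, `> 0`.  Rounded up to a whole number of steps.
#' @param init Optional initial concentration vector (default all zero).
#' @return Concentration vector over the grid at `t_end` (attribute
#'   `"x"` carries the node depths in m).
#' @export
diffuse_1d <- function(field, t_end, init = NULL) {
  stopifnot(inherits(field, "diffusion_field"))
  if (!is.finite(t_end) || t_end <= 0) stop("t_end must be > 0",
                                            call. = FALSE)
  dt_max <- field$dx^2 / (2 * field$D)
  if (field$dt > dt_max)
    stop(sprintf(
      "unstable explicit step: dt = %.4g s exceeds the maximal admissible dt = %.4g s (= dx^2 / (2 D))",
      field$dt, dt_max), call. = FALSE)
  n <- field$n_nodes
  conc <- if (is.null(init)) numeric(n) else {
    stopifnot(length(init) == n)
    as.numeric(init)
  }
  conc[1] <- field$c0
  r <- field$D * field$dt / field$dx^2
  n_steps <- ceiling(t_end / field$dt)
  idx <- 2:(n - 1)
  for (s in seq_len(n_steps)) {
    lap <- conc[idx - 1L] - 2 * conc[idx] + conc[idx + 1L]
    new_int <- conc[idx] + r * lap
    # zero-flux bottom: mirror node n-1
    conc[n] <- conc[n] + 2 * r * (conc[n - 1L] - conc[n])
    conc[idx] <- new_int
    conc[1] <- field$c0
  }
  attr(conc, "x") <- seq(0, field$length, length.out = n)
  attr(conc, "t") <- n_steps * field$dt
  conc
}

#' Front depths from the diffusion + chemistry chain
#'
#' Physics-grounded front generator: evolves dissolved CO2 into the column
#' with [diffuse_1d()], speciates every node to a pH profile, converts pH
#' to the protonated indicator fraction, and returns for each requested
#' time the depth at which that fraction crosses `level` (linearly
#' interpolated between nodes; `NA` when no crossing exists).
#'
#' @param times_s Strictly increasing times, s, all `> 0`.
#' @param field A [diffusion_field()].
#' @param sys An [equilibrium_system()]; defaults to a gel prepared at
#'   pH 8.0 ([gel_equilibrium_system()]), whose alkaline background keeps
#'   the undisturbed indicator mostly deprotonated so the front crossing
#'   exists.
#' @param indicator An [indicator_spec()].
#' @param level Indicator fraction defining the visible front (default 0.5).
#' @return Numeric vector of front depths, m (`NA` where no crossing).
#' @export
chemistry_front_depths <- function(times_s, field,
                                   sys = gel_equilibrium_system(),
                                   indicator = bromothymol_blue(),
                                   level = 0.5) {
  stopifnot(is.numeric(times_s), all(times_s > 0),
            all(diff(times_s) > 0), level > 0, level < 1)
  x <- seq(0, field$length, length.out = field$n_nodes)
  depths <- numeric(length(times_s))
  conc <- NULL
  t_prev <- 0
  for (i in seq_along(times_s)) {
    conc <- diffuse_1d(field, times_s[i] - t_prev, init = conc)
    t_prev <- t_prev + attr(conc, "t")
    frac <- fraction_protonated(speciate(pmax(conc, 0), sys)$pH, indicator)
    depths[i] <- .cross_down(x, frac, level)
  }
  depths
}

# first depth at which a decreasing profile crosses `level`, linear interp
.cross_down <- function(x, y, level) {
  below <- y < level
  if (below[1]) return(0)
  k <- which(below)[1]
  if (is.na(k)) return(NA_real_)
  x[k - 1] + (y[k - 1] - level) / (y[k - 1] - y[k]) * (x[k] - x[k - 1])
}
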