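#' Carbonate equilibrium system
#'
#' Bundles the equilibrium constants governing the dissolution of CO2 in
#' water: the first and (optional) second dissociation of carbonic acid and
#' the autoionization of water.  Dissolved CO2 hydrates to carbonic acid,
#' which dissociates to H+ and bicarbonate; the second dissociation to
#' carbonate has a much smaller constant and is negligible for the pH range
#' of interest, so it is off by default.
#'
#' @param Ka1 First dissociation constant of carbonic acid (mol/L), lumped
#'   with the hydration equilibrium so that `Ka1 = [H+][HCO3-]/[CO2(aq)]`.
#' @param Ka2 Second dissociation constant (mol/L); only used when
#'   `use_second_dissociation` is `TRUE`.
#' @param Kw Water autoionization constant (mol^2/L^2).
#' @param use_second_dissociation Include the bicarbonate/carbonate
#'   equilibrium in the charge balance?  Default `FALSE`.
#' @param alkalinity Net strong-base cation concentration (mol/L, `>= 0`)
#'   carried by the medium, e.g. from the base used to set the gel to its
#'   preparation pH.  Default 0 (pure water).  See
#'   [gel_equilibrium_system()] for a system pre-equilibrated at a target
#'   pH.
#' @return An object of class `"equilibrium_system"`.
#' @examples
#' sys <- equilibrium_system()
#' speciate(1e-3, sys)$pH
#' @export
equilibrium_system <- function(Ka1 = 4.45e-7, Ka2 = 4.69e-11, Kw = 1e-14,
                               use_second_dissociation = FALSE,
                               alkalinity = 0) {
  stopifnot(is.numeric(Ka1), length(Ka1) == 1L, Ka1 > 0,
            is.numeric(Ka2), length(Ka2) == 1L, Ka2 > 0,
            is.numeric(Kw), length(Kw) == 1L, Kw > 0,
            is.logical(use_second_dissociation),
            length(use_second_dissociation) == 1L,
            is.numeric(alkalinity), length(alkalinity) == 1L,
            alkalinity >= 0)
  structure(list(Ka1 = Ka1, Ka2 = Ka2, Kw = Kw,
                 use_second_dissociation = use_second_dissociation,
                 alkalinity = alkalinity),
            class = "equilibrium_system")
}

#' Equilibrium system of a gel prepared at a target pH
#'
#' Gels are set to a mildly alkaline preparation pH before gassing, so the
#' medium carries a net strong-base alkalinity.  This helper computes the
#' alkalinity that gives the CO2-free system the requested pH
#' (`alkalinity = Kw/h0 - h0`) and returns the corresponding
#' [equilibrium_system()].
#'
#' @param pH0 Preparation pH of the gel, in (7, 14).  Default 8.0.
#' @param ... Passed on to [equilibrium_system()].
#' @return An `"equilibrium_system"` whose CO2-free solution sits at `pH0`.
#' @export
gel_equilibrium_system <- function(pH0 = 8.0, ...) {
  stopifnot(is.numeric(pH0), length(pH0) == 1L, pH0 > 7, pH0 < 14)
  sys <- equilibrium_system(...)
  h0 <- 10^(-pH0)
  equilibrium_system(Ka1 = sys$Ka1, Ka2 = sys$Ka2, Kw = sys$Kw,
                     use_second_dissociation = sys$use_second_dissociation,
                     alkalinity = sys$Kw / h0 - h0)
}

#' @export
print.equilibrium_system <- function(x, ...) {
  cat("Carbonate equilibrium system\n")
  cat(sprintf("  Ka1 = %.4g mol/L,  Ka2 = %.4g mol/L (%s),  Kw = %.4g\n",
              x$Ka1, x$Ka2,
              if (x$use_second_dissociation) "on" else "off", x$Kw))
  invisible(x)
}

#' pH indicator specification
#'
#' Describes a pH indicator dye by its pKa, its fully protonated (acid) and
#' deprotonated (base) colours, and the pH range over which the colour
#' transition is useful.
#'
#' @param name Indicator name.
#' @param pKa Acid dissociation exponent of the dye (unitless, in (0, 14)).
#' @param acid_color,base_color RGB triples in \[0, 1\].
#' @param ideal_pH_range Length-2 numeric `(low, high)`, `low < high`.
#' @return An object of class `"indicator_spec"`.
#' @seealso [bromothymol_blue()] for the stock indicator used throughout.
#' @export
indicator_spec <- function(name, pKa, acid_color, base_color,
                           ideal_pH_range) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(pKa), length(pKa) == 1L, pKa > 0, pKa < 14)
  .check_rgb(acid_color, "acid_color")
  .check_rgb(base_color, "base_color")
  stopifnot(is.numeric(ideal_pH_range), length(ideal_pH_range) == 2L,
            ideal_pH_range[1] < ideal_pH_range[2])
  structure(list(name = name, pKa = pKa,
                 acid_color = as.numeric(acid_color),
                 base_color = as.numeric(base_color),
                 ideal_pH_range = as.numeric(ideal_pH_range)),
            class = "indicator_spec")
}

.check_rgb <- function(x, what) {
  if (!is.numeric(x) || length(x) != 3L || any(x < 0) || any(x > 1))
    stop(what, " must be an RGB triple with components in [0, 1]",
         call. = FALSE)
  invisible(x)
}

#' Bromothymol blue
#'
#' Stock indicator: yellow below ~pH 6, blue above ~pH 7.6, which brackets
#' the acidification caused by dissolving CO2 in a gel prepared at pH 8.
#' The colours are nominal camera-space values for a backlit vial.
#'
#' @return An `"indicator_spec"` with pKa 7.10 and ideal range 6.0--7.6.
#' @export
bromothymol_blue <- function() {
  indicator_spec("bromothymol blue", pKa = 7.10,
                 acid_color = c(0.92, 0.85, 0.15),
                 base_color = c(0.10, 0.35, 0.70),
                 ideal_pH_range = c(6.0, 7.6))
}

#' Speciate dissolved CO2
#'
#' Solves the proton condition for a solution containing a given total
#' dissolved CO2 concentration: `h + alkalinity = hco3 + 2*co3 + Kw/h`,
#' with `hco3 = Ka1*co2/h` and `co3 = Ka2*hco3/h` (carbonate only when the
#' system's second dissociation flag is set; alkalinity 0 for pure water).
#' The balance is monotone in `h`, so a bracketed bisection on
#' \[1e-14, 1\] mol/L finds the unique positive root (absolute tolerance
#' 1e-14 on `h`).
#'
#' @param co2_aq Dissolved CO2 concentration(s), mol/L, `>= 0`.  Vectorised.
#' @param sys An [equilibrium_system()].
#' @return A data frame of class `"speciation_state"` with columns
#'   `co2_aq`, `h_plus`, `hco3`, `co3`, `pH` (one row per input).
#' @examples
#' speciate(c(0, 1e-4, 1e-3))
#' @export
speciate <- function(co2_aq, sys = equilibrium_system()) {
  stopifnot(inherits(sys, "equilibrium_system"), is.numeric(co2_aq))
  if (any(!is.finite(co2_aq)) || any(co2_aq < 0))
    stop("co2_aq must be finite and >= 0", call. = FALSE)
  n <- length(co2_aq)
  # charge-balance residual f(h) = h + alk - hco3 - 2*co3 - Kw/h, increasing
  bal <- function(h) {
    hco3 <- sys$Ka1 * co2_aq / h
    co3 <- if (sys$use_second_dissociation) sys$Ka2 * hco3 / h else 0
    h + sys$alkalinity - hco3 - 2 * co3 - sys$Kw / h
  }
  lo <- rep(1e-14, n)
  hi <- rep(1, n)
  if (any(bal(lo) > 0) || any(bal(hi) < 0))
    stop("speciation root not bracketed in [1e-14, 1] mol/L; ",
         "residuals at bracket ends: ",
         paste(signif(range(c(bal(lo), bal(hi))), 3), collapse = ", "),
         call. = FALSE)
  for (i in seq_len(200)) {      # 2^-200 << 1e-14: always converges
    mid <- (lo + hi) / 2
    up <- bal(mid) > 0
    hi[up] <- mid[up]
    lo[!up] <- mid[!up]
    if (all(hi - lo < 1e-14)) break
  }
  h <- (lo + hi) / 2
  hco3 <- sys$Ka1 * co2_aq / h
  co3 <- if (sys$use_second_dissociation) sys$Ka2 * hco3 / h else
    rep(0, n)
  out <- data.frame(co2_aq = co2_aq, h_plus = h, hco3 = hco3, co3 = co3,
                    pH = -log10(h))
  class(out) <- c("speciation_state", "data.frame")
  out
}

#' Protonated fraction of an indicator
#'
#' Henderson--Hasselbalch fraction of the indicator in its protonated
#' (acid-coloured) form: `1 / (1 + 10^(pH - pKa))`.  Strictly decreasing
#' and continuous in pH.
#'
#' @param pH pH value(s) in \[0, 14\].  Vectorised.
#' @param indicator An [indicator_spec()].
#' @return Fraction(s) in \[0, 1\].
#' @export
fraction_protonated <- function(pH, indicator = bromothymol_blue()) {
  stopifnot(inherits(indicator, "indicator_spec"), is.numeric(pH))
  if (any(!is.finite(pH)) || any(pH < 0) || any(pH > 14))
    stop("pH must lie in [0, 14]", call. = FALSE)
  1 / (1 + 10^(pH - indicator$pKa))
}
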