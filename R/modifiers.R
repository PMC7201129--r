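#' Shear stress growth response
#'
#' Piecewise-linear response of neotissue growth to flow-induced wall shear
#' stress tau (Pa): growth proceeds at half speed at zero shear, rises
#' linearly to the optimal plateau on `[a1, a2)`, declines linearly back to
#' zero on `[a2, a3)`, and stops entirely for tau at or above `a3`
#' (detrimental shear). Continuous on `[0, Inf)`.
#'
#' The declining branch is `(a3 - tau)/(a3 - a2)`, which equals 1 at `a2`
#' and 0 at `a3`.
#'
#' @param tau Wall shear stress (Pa), non-negative. Vectorized.
#' @param params A [kinetic_parameters()] object (uses `a1`, `a2`, `a3`).
#' @return Modifier value(s) in `[0, 1]`.
#' @export
#' @examples
#' p <- kinetic_parameters()
#' shear_modifier(c(0, 0.02, 0.04, 0.06), p)
shear_modifier <- function(tau, params = kinetic_parameters()) {
  if (any(!is.finite(tau)) || any(tau < 0)) {
    stop("shear stress must be finite and >= 0", call. = FALSE)
  }
  a1 <- params$a1; a2 <- params$a2; a3 <- params$a3
  out <- numeric(length(tau))
  low <- tau < a1
  opt <- tau >= a1 & tau < a2
  dec <- tau >= a2 & tau < a3
  out[low] <- 0.5 + 0.5 * tau[low] / a1
  out[opt] <- 1
  out[dec] <- (a3 - tau[dec]) / (a3 - a2)
  out
}

#' Curvature growth response
#'
#' Growth speed is proportional to the (normalized) mean curvature of the
#' neotissue-void interface where that curvature is positive (concave voids
#' drive growth); flat or convex interfaces contribute nothing.
#'
#' @param kappa Normalized curvature. Vectorized; must be finite.
#' @return `kappa` where positive, else 0.
#' @export
curvature_modifier <- function(kappa) {
  if (any(!is.finite(kappa))) stop("curvature must be finite", call. = FALSE)
  pmax(kappa, 0)
}

#' Oxygen availability modifier
#'
#' Michaelis-Menten saturation `Co/(Ko + Co)`: strictly increasing in the
#' oxygen concentration, 0.5 at the Michaelis constant, saturating at 1.
#'
#' @param Co Oxygen concentration (mol/m^3), non-negative. Vectorized.
#' @param params A [kinetic_parameters()] object (uses `Ko`).
#' @return Modifier value(s) in `[0, 1)`.
#' @export
oxygen_modifier <- function(Co, params = kinetic_parameters()) {
  if (any(!is.finite(Co)) || any(Co < 0)) {
    stop("oxygen concentration must be finite and >= 0", call. = FALSE)
  }
  Co / (params$Ko + Co)
}

#' Glucose availability modifier
#'
#' Michaelis-Menten saturation `Cg/(Kg + Cg)`; see [oxygen_modifier()].
#'
#' @param Cg Glucose concentration (mol/m^3), non-negative. Vectorized.
#' @param params A [kinetic_parameters()] object (uses `Kg`).
#' @return Modifier value(s) in `[0, 1)`.
#' @export
glucose_modifier <- function(Cg, params = kinetic_parameters()) {
  if (any(!is.finite(Cg)) || any(Cg < 0)) {
    stop("glucose concentration must be finite and >= 0", call. = FALSE)
  }
  Cg / (params$Kg + Cg)
}

#' Medium pH from lactate concentration
#'
#' Affine acidification relation `pH = 7.4 - 0.0406 * Cla`: fresh medium is
#' at pH 7.4 and every mol/m^3 of accumulated lactate lowers it by 0.0406
#' units. No clamping is applied.
#'
#' @param Cla Lactate concentration (mol/m^3), non-negative. Vectorized.
#' @return pH value(s).
#' @export
ph_from_lactate <- function(Cla) {
  if (any(!is.finite(Cla)) || any(Cla < 0)) {
    stop("lactate concentration must be finite and >= 0", call. = FALSE)
  }
  7.4 - 0.0406 * Cla
}

#' pH growth response
#'
#' Acidification penalty on growth: no penalty above pH 7.1, total growth
#' arrest at or below pH 6.375, and a linear ramp `(4/3) * pH - 8.5` in
#' between (0 at pH 6.375, 0.967 just below 7.1, with the small jump to 1
#' at 7.1 retained from the underlying dose-response). Output is clipped to
#' `[0, 1]` to guard the ramp endpoint under floating point.
#'
#' @param pH Medium pH. Vectorized; must be finite.
#' @return Modifier value(s) in `[0, 1]`.
#' @export
ph_modifier <- function(pH) {
  if (any(!is.finite(pH))) stop("pH must be finite", call. = FALSE)
  out <- numeric(length(pH))
  out[pH >= 7.1] <- 1
  mid <- pH >= 6.375 & pH < 7.1
  out[mid] <- 4 / 3 * pH[mid] - 8.5
  pmin(pmax(out, 0), 1)
}

#' Growth-factor proliferation gain
#'
#' Saturating stimulation of cell proliferation by the growth factor:
#' `alpha2 * gf/(alpha3 + gf)`, strictly increasing in the dose with
#' ceiling `alpha2` and half-saturation at `alpha3`.
#'
#' @param gf Growth-factor concentration (ng/ml), non-negative. Vectorized.
#' @param params A [kinetic_parameters()] object (uses `alpha2`, `alpha3`).
#' @return Gain value(s) in `[0, alpha2)`.
#' @export
gf_proliferation_gain <- function(gf, params = kinetic_parameters()) {
  if (any(!is.finite(gf)) || any(gf < 0)) {
    stop("growth-factor concentration must be finite and >= 0", call. = FALSE)
  }
  params$alpha2 * gf / (params$alpha3 + gf)
}

#' Growth-factor attenuation of matrix production
#'
#' The growth factor suppresses ECM deposition: the matrix production rate
#' is scaled by `alpha1/(1 + gf)`, strictly decreasing in the dose from
#' `alpha1` at zero dose toward 0 at large doses.
#'
#' @param gf Growth-factor concentration (ng/ml), non-negative. Vectorized.
#' @param params A [kinetic_parameters()] object (uses `alpha1`).
#' @return Attenuation value(s) in `(0, alpha1]`.
#' @export
gf_matrix_attenuation <- function(gf, params = kinetic_parameters()) {
  if (any(!is.finite(gf)) || any(gf < 0)) {
    stop("growth-factor concentration must be finite and >= 0", call. = FALSE)
  }
  params$alpha1 / (1 + gf)
}
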