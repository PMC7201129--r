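#' State vector constructor
#'
#' The six dynamic quantities of the culture model, in canonical order:
#' oxygen `Co`, glucose `Cg` and lactate `Cla` concentrations (mol/m^3),
#' ECM and cell volume fractions `V_ecm`, `V_cell` (of available space),
#' and growth-factor concentration `gf` (ng/ml). pH is derived, not a
#' state: `pH = 7.4 - 0.0406 * Cla`.
#'
#' @param Co,Cg,Cla Species concentrations (mol/m^3), non-negative.
#' @param V_ecm,V_cell Volume fractions; `V_cell + V_ecm` must not exceed 1.
#' @param gf Growth-factor concentration (ng/ml), non-negative.
#' @return A named numeric vector of length 6.
#' @export
culture_state <- function(Co, Cg, Cla, V_ecm, V_cell, gf) {
  s <- c(Co = Co, Cg = Cg, Cla = Cla, V_ecm = V_ecm, V_cell = V_cell, gf = gf)
  validate_culture_state(s)
  s
}

validate_culture_state <- function(state, tol = 1e-8) {
  if (!all(is.finite(state))) {
    stop("culture state must be finite; got: ",
         paste(sprintf("%s=%g", names(state), state), collapse = ", "),
         call. = FALSE)
  }
  if (any(state < -tol)) {
    stop("culture state components must be >= 0", call. = FALSE)
  }
  if (state[["V_cell"]] + state[["V_ecm"]] > 1 + tol) {
    stop("V_cell + V_ecm must not exceed the available space (1)",
         call. = FALSE)
  }
  invisible(state)
}

#' Time derivative of the culture state
#'
#' Right-hand side of the six-variable model, evaluated at one state. All
#' growth and consumption terms share the modulator product
#' `P = fs(tau) * fc(kappa) * h1(Co) * h2(Cg) * h3(pH)` built from the
#' shear, curvature, oxygen, glucose and pH responses; geometry enters
#' through the closures in [environment_model()] evaluated at the filled
#' fraction `V_fill = V_cell + V_ecm`.
#'
#' The balances are (with `s = rate_scale`, `phi = phi_cells`,
#' `space = v_total - V_cell - V_ecm`):
#' \itemize{
#'   \item `dV_ecm/dt  =  s * A1 * P * V_cell * space * alpha1/(1 + gf)`
#'   \item `dV_cell/dt =  s * A2 * P * V_cell * V_ecm * space * alpha2*gf/(alpha3 + gf)`
#'   \item `dCo/dt  = -s * beta1 * V_fill * phi * Vo * Co/(Ko + gamma*Co)`
#'   \item `dCg/dt  = -s * beta2 * V_fill * phi * Vg * Cg/(Kg + Cg)`
#'   \item `dCla/dt = -(2/beta2) * dCg/dt` (two lactate per glucose)
#'   \item `dgf/dt  = -lam * gf`
#' }
#' Cell growth requires ECM (`dV_cell/dt = 0` while `V_ecm = 0`), which
#' produces the lag phase seen in culture; both fractions stall when the
#' scaffold is full (`space = 0`). Derivatives are per second.
#'
#' @param state Named state vector as from [culture_state()].
#' @param params A [kinetic_parameters()] object.
#' @param env An [environment_model()] object.
#' @param scaffold A [scaffold_spec()] object.
#' @param flow_rate_ml_min Optional flow-rate override (ml/min); defaults
#'   to the scaffold's flow rate.
#' @return Named numeric vector of time derivatives (per second), same
#'   order as the state.
#' @export
#' @examples
#' d <- state_derivative(culture_state(0.192, 25, 0, 0, 0.0139, 1))
#' d[["V_cell"]]  # zero: no ECM yet (lag phase)
state_derivative <- function(state,
                             params = kinetic_parameters(),
                             env = environment_model(),
                             scaffold = scaffold_spec(),
                             flow_rate_ml_min = NULL) {
  validate_culture_state(state)
  if (is.null(flow_rate_ml_min)) flow_rate_ml_min <- scaffold$flow_rate_ml_min
  Co <- state[["Co"]]; Cg <- state[["Cg"]]; Cla <- state[["Cla"]]
  V_ecm <- state[["V_ecm"]]; V_cell <- state[["V_cell"]]; gf <- state[["gf"]]

  v_fill <- V_cell + V_ecm
  tau <- env$shear_fn(v_fill, flow_rate_ml_min)
  kappa <- env$curvature_fn(v_fill)
  P <- shear_modifier(tau, params) *
    curvature_modifier(kappa) *
    oxygen_modifier(Co, params) *
    glucose_modifier(Cg, params) *
    ph_modifier(ph_from_lactate(Cla))

  s <- params$rate_scale
  space <- scaffold$v_total - V_cell - V_ecm
  uptake_g <- s * params$beta2 * v_fill * params$phi_cells * params$Vg *
    Cg / (params$Kg + Cg)

  c(
    Co = -s * params$beta1 * v_fill * params$phi_cells * params$Vo *
      Co / (params$Ko + params$gamma * Co),
    Cg = -uptake_g,
    Cla = 2 / params$beta2 * uptake_g,
    V_ecm = s * params$A1 * P * V_cell * space *
      gf_matrix_attenuation(gf, params),
    V_cell = s * params$A2 * P * V_cell * V_ecm * space *
      gf_proliferation_gain(gf, params),
    gf = -params$lam * gf
  )
}
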