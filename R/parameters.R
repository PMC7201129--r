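#' Kinetic parameter set for the culture model
#'
#' Bundles every rate constant, Michaelis constant, shear threshold and
#' growth-factor response constant of the homogenized growth model. Defaults
#' are the calibrated reference values for human periosteum-derived cells in a
#' perfusion bioreactor at a flow rate of 0.04 ml/min.
#'
#' Time base: `Vo`, `Vg` and `lam` are genuinely per-second quantities
#' (consumption per cell per second; first-order decay). The lumped scales
#' `A1`, `A2`, `beta1`, `beta2` absorb an unresolved unit mismatch in the
#' species and growth balances; `rate_scale` is a single dimensionless
#' multiplier applied to all four of them (and to the stoichiometrically
#' coupled lactate production term) so that the model can be pinned to an
#' observed cell-count anchor without disturbing the published ratios between
#' them. See [normalize_reference_configuration()].
#'
#' @param A1 ECM production rate scale (lumped, dimensionless time base).
#' @param A2 Cell proliferation rate scale (lumped).
#' @param a1,a2,a3 Shear stress thresholds (Pa) of the piecewise shear
#'   response: growth is sub-optimal below `a1`, optimal on `[a1, a2)`,
#'   declines on `[a2, a3)` and stops for shear at or above `a3`.
#'   Must satisfy `0 < a1 < a2 < a3`.
#' @param Vo Oxygen consumption rate per cell (mol/cell/s).
#' @param Vg Glucose consumption rate per cell (mol/cell/s).
#' @param Ko Oxygen Michaelis constant (mol/m^3).
#' @param Kg Glucose Michaelis constant (mol/m^3).
#' @param beta1,beta2 Lumped species-balance scale factors (dimensionless)
#'   for the oxygen and glucose balances.
#' @param gamma Coefficient of the oxygen concentration in the oxygen
#'   Michaelis denominator (dimensionless).
#' @param phi_cells Cell density within the neotissue (cells/m^3).
#' @param lam Growth-factor decay rate (1/s); the default corresponds to a
#'   half-life of 1.5 h, `log(2)/5400`.
#' @param alpha1 ECM-production attenuation constant (ng/ml): matrix
#'   deposition is scaled by `alpha1/(1 + gf)`.
#' @param alpha2 Ceiling of the proliferation gain (dimensionless): cell
#'   growth is scaled by `alpha2 * gf/(alpha3 + gf)`.
#' @param alpha3 Half-saturation dose of the proliferation gain (ng/ml).
#' @param rate_scale Dimensionless multiplier applied to `A1`, `A2`,
#'   `beta1`, `beta2` and the lactate production term (default 1).
#'
#' @return An object of class `kinetic_parameters` (a validated named list).
#' @seealso [state_derivative()], [normalize_reference_configuration()]
#' @export
#' @examples
#' p <- kinetic_parameters()
#' p$lam * 5400 / log(2)  # decay rate encodes a 1.5 h half-life
kinetic_parameters <- function(A1 = 0.216,
                               A2 = 5.612e12,
                               a1 = 0.01,
                               a2 = 0.03,
                               a3 = 0.05,
                               Vo = 1.09e-17,
                               Vg = 9.5e-17,
                               Ko = 1.82e-3,
                               Kg = 0.3,
                               beta1 = 255,
                               beta2 = 3.6e5,
                               gamma = 0.6716,
                               phi_cells = 2.5e13,
                               lam = log(2) / 5400,
                               alpha1 = 0.975,
                               alpha2 = 12.09,
                               alpha3 = 0.1,
                               rate_scale = 1) {
  p <- list(
    A1 = A1, A2 = A2, a1 = a1, a2 = a2, a3 = a3,
    Vo = Vo, Vg = Vg, Ko = Ko, Kg = Kg,
    beta1 = beta1, beta2 = beta2, gamma = gamma,
    phi_cells = phi_cells, lam = lam,
    alpha1 = alpha1, alpha2 = alpha2, alpha3 = alpha3,
    rate_scale = rate_scale
  )
  validate_kinetic_parameters(p)
  structure(p, class = "kinetic_parameters")
}

validate_kinetic_parameters <- function(p) {
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1L && is.finite(x),
                logical(1))
  if (!all(num)) {
    stop("kinetic parameters must be finite numeric scalars: ",
         paste(names(p)[!num], collapse = ", "), call. = FALSE)
  }
  # A1, A2 and rate_scale may be zero (growth switched off); the rest are
  # genuine physical constants and must be strictly positive
  zero_ok <- c("A1", "A2", "rate_scale")
  v <- unlist(p)
  pos <- ifelse(names(v) %in% zero_ok, v >= 0, v > 0)
  if (!all(pos)) {
    stop("kinetic parameters must be strictly positive: ",
         paste(names(p)[!pos], collapse = ", "), call. = FALSE)
  }
  if (!(p$a1 < p$a2 && p$a2 < p$a3)) {
    stop("shear thresholds must satisfy a1 < a2 < a3", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.kinetic_parameters <- function(x, ...) {
  cat("Kinetic parameters (homogenized perfusion culture model)\n")
  cat(sprintf("  growth scales: A1 = %.4g, A2 = %.4g (rate_scale = %.4g)\n",
              x$A1, x$A2, x$rate_scale))
  cat(sprintf("  shear thresholds [Pa]: a1 = %g, a2 = %g, a3 = %g\n",
              x$a1, x$a2, x$a3))
  cat(sprintf("  uptake: Vo = %.3g, Vg = %.3g mol/cell/s; Ko = %.3g, Kg = %.3g mol/m^3\n",
              x$Vo, x$Vg, x$Ko, x$Kg))
  cat(sprintf("  lumped scales: beta1 = %g, beta2 = %g; gamma = %g; phi_cells = %.3g\n",
              x$beta1, x$beta2, x$gamma, x$phi_cells))
  cat(sprintf("  growth factor: lam = %.5g 1/s (t1/2 = %.3g h), alpha1 = %g, alpha2 = %g, alpha3 = %g\n",
              x$lam, log(2) / x$lam / 3600, x$alpha1, x$alpha2, x$alpha3))
  invisible(x)
}

#' Scaffold geometry and seeding specification
#'
#' Fixes the conversion between cell volume fraction and cell count. The
#' available pore space is normalized to `v_total = 1`; the seeded fraction
#' (default 1.39\% of available space) corresponds to `cells_at_seed` cells
#' (default 1e5), pinning a constant cells-per-fraction conversion. The
#' single-cell volume is that of a 20 micrometre diameter sphere,
#' about 4.2e3 um^3.
#'
#' @param v_total Total available volume fraction (normalized units; 1).
#' @param single_cell_volume_um3 Volume of one cell (um^3).
#' @param cells_at_seed Number of cells seeded on the scaffold.
#' @param seed_fraction Cell volume fraction at seeding (of available space).
#' @param flow_rate_ml_min Perfusion flow rate (ml/min); 0 for static culture.
#' @return An object of class `scaffold_spec`.
#' @export
#' @examples
#' cells_from_fraction(0.0139, scaffold_spec())  # 1e5 seeded cells
scaffold_spec <- function(v_total = 1,
                          single_cell_volume_um3 = 4 / 3 * pi * 10^3,
                          cells_at_seed = 1e5,
                          seed_fraction = 0.0139,
                          flow_rate_ml_min = 0.04) {
  sphere <- 4 / 3 * pi * 10^3
  if (abs(single_cell_volume_um3 - sphere) / sphere > 0.01) {
    stop("single_cell_volume_um3 must equal the volume of a 20 um sphere ",
         sprintf("(%.4g um^3) within 1%%", sphere), call. = FALSE)
  }
  if (v_total <= 0 || seed_fraction <= 0 || seed_fraction >= v_total) {
    stop("seed_fraction must lie in (0, v_total)", call. = FALSE)
  }
  if (cells_at_seed <= 0) stop("cells_at_seed must be positive", call. = FALSE)
  if (flow_rate_ml_min < 0) stop("flow_rate_ml_min must be >= 0", call. = FALSE)
  structure(
    list(v_total = v_total,
         single_cell_volume_um3 = single_cell_volume_um3,
         cells_at_seed = cells_at_seed,
         seed_fraction = seed_fraction,
         flow_rate_ml_min = flow_rate_ml_min),
    class = "scaffold_spec"
  )
}

#' @export
print.scaffold_spec <- function(x, ...) {
  cat("Scaffold specification\n")
  cat(sprintf("  available space (normalized): %g\n", x$v_total))
  cat(sprintf("  seeding: %.3g cells at fraction %.4g (%.3g um^3 per cell)\n",
              x$cells_at_seed, x$seed_fraction, x$single_cell_volume_um3))
  cat(sprintf("  flow rate: %g ml/min\n", x$flow_rate_ml_min))
  invisible(x)
}

#' Geometry and flow closures for the homogenized model
#'
#' The spatially resolved precursor of this model computes interface
#' curvature and wall shear stress from the actual neotissue geometry; the
#' homogenized model replaces them with closures in the filled fraction
#' `V_cell + V_ecm`. Both closures are injectable strategy functions.
#'
#' Defaults model a shrinking cylindrical pore: normalized curvature
#' `kappa(fill) = sqrt((1 - v0)/(1 - fill))` (equal to 1 at the seeded
#' fraction `v0`) and Poiseuille-type wall shear
#' `tau(fill, Q) = tau0 * (Q/q_ref) * ((1 - v0)/(1 - fill))^1.5`,
#' which keeps shear in the sub-optimal response branch at the reference
#' low flow rate and lets it rise as the pores fill.
#'
#' @param curvature_fn Function of the filled fraction returning normalized
#'   curvature (non-negative, non-decreasing).
#' @param shear_fn Function of (filled fraction, flow rate in ml/min)
#'   returning wall shear stress in Pa (non-negative, non-decreasing in the
#'   filled fraction, zero at zero flow).
#' @param v0 Seeded fraction at which curvature is normalized to 1.
#' @param tau0 Shear stress (Pa) at the seeded fraction and reference flow.
#' @param q_ref Reference flow rate (ml/min).
#' @return An object of class `environment_model`.
#' @export
environment_model <- function(curvature_fn = NULL, shear_fn = NULL,
                              v0 = 0.0139, tau0 = 0.005, q_ref = 0.04) {
  if (is.null(curvature_fn)) {
    force(v0)
    curvature_fn <- function(fill) {
      fill <- pmin(fill, 1 - 1e-9)
      sqrt((1 - v0) / (1 - fill))
    }
  }
  if (is.null(shear_fn)) {
    force(tau0); force(q_ref)
    shear_fn <- function(fill, flow_rate_ml_min) {
      fill <- pmin(fill, 1 - 1e-9)
      tau0 * (flow_rate_ml_min / q_ref) * ((1 - v0) / (1 - fill))^1.5
    }
  }
  stopifnot(is.function(curvature_fn), is.function(shear_fn))
  grid <- seq(0.01, 0.95, by = 0.02)
  kap <- vapply(grid, curvature_fn, numeric(1))
  if (any(!is.finite(kap)) || any(kap < 0) || any(diff(kap) < -1e-12)) {
    stop("curvature_fn must be non-negative and non-decreasing in the filled fraction",
         call. = FALSE)
  }
  tau <- vapply(grid, shear_fn, numeric(1), flow_rate_ml_min = 0.04)
  if (any(!is.finite(tau)) || any(tau < 0) || any(diff(tau) < -1e-12)) {
    stop("shear_fn must be non-negative and non-decreasing in the filled fraction",
         call. = FALSE)
  }
  if (abs(shear_fn(0.3, 0)) > 1e-12) {
    stop("shear_fn must be zero at zero flow rate", call. = FALSE)
  }
  structure(list(curvature_fn = curvature_fn, shear_fn = shear_fn),
            class = "environment_model")
}

#' Fresh-medium composition
#'
#' Concentrations of the refreshed species in fresh culture medium; these
#' are also the initial conditions of a run. Defaults: glucose 25 mol/m^3,
#' oxygen 0.192 mol/m^3, no lactate, growth factor at the 1 ng/ml baseline.
#'
#' @param glucose0 Fresh-medium glucose concentration (mol/m^3).
#' @param oxygen0 Fresh-medium oxygen concentration (mol/m^3).
#' @param lactate0 Fresh-medium lactate concentration (mol/m^3).
#' @param gf0 Fresh-medium growth-factor concentration (ng/ml).
#' @return An object of class `medium_spec`.
#' @export
medium_spec <- function(glucose0 = 25, oxygen0 = 0.192, lactate0 = 0, gf0 = 1) {
  vals <- c(glucose0 = glucose0, oxygen0 = oxygen0,
            lactate0 = lactate0, gf0 = gf0)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("medium concentrations must be finite and >= 0", call. = FALSE)
  }
  structure(as.list(vals), class = "medium_spec")
}

#' Medium refreshment regimen
#'
#' The fed-batch exchange schedule: every `period_hours` a fraction
#' `fraction` of the reservoir is replaced by fresh medium, for
#' `duration_days` of culture, at perfusion flow `flow_rate_ml_min`.
#' These are the decision variables of the culture optimization.
#'
#' @param period_hours Refreshment period p (h).
#' @param fraction Fraction a of the medium exchanged per event, in `[0, 1]`.
#' @param duration_days Total culture duration d (days).
#' @param flow_rate_ml_min Perfusion flow rate (ml/min); `NA` to use the
#'   scaffold's flow rate.
#' @return An object of class `refreshment_regime`.
#' @export
#' @examples
#' refreshment_regime(48, 1, 28)  # full exchange every 2 days, 4 weeks
refreshment_regime <- function(period_hours, fraction, duration_days,
                               flow_rate_ml_min = NA_real_) {
  if (!is.finite(period_hours) || period_hours <= 0) {
    stop("period_hours must be > 0", call. = FALSE)
  }
  if (!is.finite(fraction) || fraction < 0 || fraction > 1) {
    stop("fraction must lie in [0, 1]", call. = FALSE)
  }
  if (!is.finite(duration_days) || duration_days <= 0) {
    stop("duration_days must be > 0", call. = FALSE)
  }
  structure(
    list(period_hours = period_hours, fraction = fraction,
         duration_days = duration_days, flow_rate_ml_min = flow_rate_ml_min),
    class = "refreshment_regime"
  )
}

#' @export
print.refreshment_regime <- function(x, ...) {
  cat(sprintf("Refreshment regimen: every %g h exchange %.0f%%, %g days",
              x$period_hours, 100 * x$fraction, x$duration_days))
  if (is.finite(x$flow_rate_ml_min)) {
    cat(sprintf(", flow %g ml/min", x$flow_rate_ml_min))
  }
  cat("\n")
  invisible(x)
}

#' ODE solver options
#'
#' @param method Integration method passed to [deSolve::ode()]; the default
#'   `"lsoda"` switches automatically between stiff and non-stiff steppers.
#' @param rtol Relative tolerance.
#' @param atol Absolute tolerance.
#' @return An object of class `solver_options`.
#' @export
solver_options <- function(method = "lsoda", rtol = 1e-8, atol = 1e-10) {
  stopifnot(is.character(method), length(method) == 1L,
            is.finite(rtol), rtol > 0, is.finite(atol), atol > 0)
  structure(list(method = method, rtol = rtol, atol = atol),
            class = "solver_options")
}
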