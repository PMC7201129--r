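#' Apply one medium-refreshment event to a culture state
#'
#' Replaces a fraction `a` of the reservoir by fresh medium: glucose,
#' lactate and growth factor become the percentage-weighted average
#' `(1 - a) * current + a * fresh`. Oxygen is not reinitialized (the
#' set-up leaks oxygen continuously, so exchanging medium does not change
#' the dissolved oxygen level), and the tissue fractions are untouched.
#'
#' @param state Named culture state vector (see [culture_state()]).
#' @param medium A [medium_spec()] object.
#' @param fraction Fraction of the medium exchanged, in `[0, 1]`.
#' @return The post-event state vector.
#' @export
#' @examples
#' s <- culture_state(0.15, 5, 12, 0.01, 0.05, 0.2)
#' apply_refreshment(s, medium_spec(), 0.5)[["Cg"]]  # 15
apply_refreshment <- function(state, medium = medium_spec(), fraction) {
  if (!is.finite(fraction) || fraction < 0 || fraction > 1) {
    stop("refreshment fraction must lie in [0, 1]", call. = FALSE)
  }
  state[["Cg"]] <- (1 - fraction) * state[["Cg"]] + fraction * medium$glucose0
  state[["Cla"]] <- (1 - fraction) * state[["Cla"]] + fraction * medium$lactate0
  state[["gf"]] <- (1 - fraction) * state[["gf"]] + fraction * medium$gf0
  state
}

#' Convert between cell volume fraction and cell count
#'
#' Linear conversion pinned by the seeding condition: the seeded fraction
#' (default 1.39\% of available space) corresponds to the seeded cell
#' count (default 1e5), so `cells = fraction * cells_at_seed/seed_fraction`.
#' `fraction_from_cells()` is the exact inverse.
#'
#' @param fraction Cell volume fraction(s), non-negative.
#' @param cells Cell count(s), non-negative.
#' @param scaffold A [scaffold_spec()] object.
#' @return Cell count(s), or volume fraction(s) for the inverse.
#' @export
#' @examples
#' cells_from_fraction(0.0959, scaffold_spec())  # about 6.9e5 cells
cells_from_fraction <- function(fraction, scaffold = scaffold_spec()) {
  if (any(!is.finite(fraction)) || any(fraction < 0)) {
    stop("fraction must be finite and >= 0", call. = FALSE)
  }
  fraction * scaffold$cells_at_seed / scaffold$seed_fraction
}

#' @rdname cells_from_fraction
#' @export
fraction_from_cells <- function(cells, scaffold = scaffold_spec()) {
  if (any(!is.finite(cells)) || any(cells < 0)) {
    stop("cells must be finite and >= 0", call. = FALSE)
  }
  cells * scaffold$seed_fraction / scaffold$cells_at_seed
}

# Event times of a regimen, in hours. Events fall at every multiple of the
# period strictly before the end of culture; an exchange at the final
# instant could not affect any outcome and is excluded.
refreshment_times <- function(regime) {
  t_end <- regime$duration_days * 24
  n <- floor(t_end / regime$period_hours + 1e-9)
  times <- regime$period_hours * seq_len(n)
  times[times < t_end - 1e-9]
}

#' Simulate a perfusion culture with periodic medium refreshment
#'
#' Integrates the six-variable model (see [state_derivative()]) from the
#' seeding state over the culture duration, applying a medium-refreshment
#' event at every multiple of the regimen period (strictly before the end
#' of culture). The integrator is restarted at each event (hard
#' discontinuity); both the pre-event and post-event states are recorded
#' with the same timestamp, the post-event row flagged.
#'
#' The initial state is assembled from the medium (oxygen, glucose,
#' lactate, growth factor at their fresh-medium values) and the scaffold
#' (cell fraction at the seeded fraction, no ECM).
#'
#' @param params A [kinetic_parameters()] object.
#' @param env An [environment_model()] object.
#' @param scaffold A [scaffold_spec()] object.
#' @param medium A [medium_spec()] object.
#' @param regime A [refreshment_regime()] object.
#' @param solver A [solver_options()] object.
#' @param output_dt Output sampling step (h); event times are always
#'   included in addition.
#' @param extra_times Extra output times (h) to include in the grid.
#' @return A `culture_trajectory`: a data frame with columns `time_h`,
#'   `Co`, `Cg`, `Cla`, `pH`, `V_cell`, `V_ecm`, `gf`, `cells`,
#'   `event_flag` (1 on post-event rows), plus attributes `events`
#'   (event log data frame) and `config` (the run configuration).
#' @export
#' @examples
#' traj <- simulate_culture(regime = refreshment_regime(48, 1, 2))
#' tail(traj, 1)$cells
simulate_culture <- function(params = kinetic_parameters(),
                             env = environment_model(),
                             scaffold = scaffold_spec(),
                             medium = medium_spec(),
                             regime = refreshment_regime(48, 1, 28),
                             solver = solver_options(),
                             output_dt = 1,
                             extra_times = NULL) {
  flow <- if (is.finite(regime$flow_rate_ml_min)) {
    regime$flow_rate_ml_min
  } else {
    scaffold$flow_rate_ml_min
  }
  t_end <- regime$duration_days * 24
  events <- refreshment_times(regime)
  bounds <- c(0, events, t_end)

  state <- culture_state(Co = medium$oxygen0, Cg = medium$glucose0,
                         Cla = medium$lactate0, V_ecm = 0,
                         V_cell = scaffold$seed_fraction, gf = medium$gf0)

  # deSolve integrates over hours; the model RHS is per second.
  rhs <- make_rhs(params, env, scaffold, flow)

  grid_all <- sort(unique(c(seq(0, t_end, by = output_dt), t_end,
                            extra_times)))
  grid_all <- grid_all[grid_all >= 0 & grid_all <= t_end]

  rows <- vector("list", length(bounds))
  rows[[1]] <- data.frame(time_h = 0, t(state), event_flag = 0L)
  for (k in seq_len(length(bounds) - 1L)) {
    t0 <- bounds[k]; t1 <- bounds[k + 1L]
    times <- sort(unique(c(t0, grid_all[grid_all > t0 & grid_all < t1], t1)))
    sol <- deSolve::ode(y = state, times = times, func = rhs, parms = NULL,
                        method = solver$method, rtol = solver$rtol,
                        atol = solver$atol)
    diagn <- attributes(sol)$istate
    if (!is.null(diagn) && diagn[1] < 0) {
      stop(sprintf("integration failed in [%g, %g] h; last valid time %g h",
                   t0, t1, max(sol[, "time"])), call. = FALSE)
    }
    seg <- as.data.frame(sol)[-1, , drop = FALSE]
    names(seg)[1] <- "time_h"
    seg$event_flag <- 0L
    state <- sol[nrow(sol), -1]
    state[state < 0 & state > -solver$atol * 10] <- 0
    validate_culture_state(state, tol = 1e-6)
    if (k + 1L < length(bounds)) {
      # refreshment at t1: record pre-event state, then the exchanged state
      state <- apply_refreshment(state, medium, regime$fraction)
      post <- data.frame(time_h = t1, t(state), event_flag = 1L)
      seg <- rbind(seg, post)
    }
    rows[[k + 1L]] <- seg
  }

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$pH <- ph_from_lactate(pmax(out$Cla, 0))
  out$cells <- cells_from_fraction(out$V_cell, scaffold)
  out <- out[, c("time_h", "Co", "Cg", "Cla", "pH", "V_cell", "V_ecm",
                 "gf", "cells", "event_flag")]

  ev <- data.frame(time_h = events,
                   fraction = rep(regime$fraction, length(events)))
  structure(out,
            events = ev,
            config = list(params = params, scaffold = scaffold,
                          medium = medium, regime = regime,
                          flow_rate_ml_min = flow, solver = solver),
            class = c("culture_trajectory", "data.frame"))
}

#' @export
print.culture_trajectory <- function(x, ...) {
  cfg <- attr(x, "config")
  fin <- x[nrow(x), ]
  cat("Culture trajectory\n")
  if (!is.null(cfg)) {
    cat(sprintf("  regimen: every %g h exchange %.0f%%, %g days, flow %g ml/min\n",
                cfg$regime$period_hours, 100 * cfg$regime$fraction,
                cfg$regime$duration_days, cfg$flow_rate_ml_min))
  }
  cat(sprintf("  %d samples, %d refreshment events\n",
              nrow(x), nrow(attr(x, "events"))))
  cat(sprintf("  final state (t = %g h): V_cell = %.4f (%.3g cells), V_ecm = %.3g, Cg = %.2f, pH = %.2f\n",
              fin$time_h, fin$V_cell, fin$cells, fin$V_ecm, fin$Cg, fin$pH))
  invisible(x)
}

#' Write / read a culture trajectory
#'
#' Writes the trajectory table to CSV (columns `time_h, Co, Cg, Cla, pH,
#' V_cell, V_ecm, gf, cells, event_flag`) and a JSON metadata sidecar
#' (`<path>.meta.json`) holding the full run configuration and the package
#' version.
#'
#' @param traj A `culture_trajectory` from [simulate_culture()].
#' @param path Output CSV path.
#' @return `path`, invisibly (`read_trajectory` returns the data frame).
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  cfg <- attr(traj, "config")
  meta <- list(
    software = list(package = "perfusim",
                    version = as.character(utils::packageVersion("perfusim"))),
    config = serialize_config_blocks(cfg),
    n_events = nrow(attr(traj, "events"))
  )
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  utils::read.csv(path)
}

# Lean right-hand side for the integrator: same model as
# state_derivative() (which remains the reference implementation and is
# pinned to this one by tests), with the constants folded in and the
# per-second rates converted to per-hour. Tiny negative excursions from
# integrator trial steps are zeroed; anything worse aborts.
make_rhs <- function(params, env, scaffold, flow) {
  a1 <- params$a1; a2 <- params$a2; a3 <- params$a3
  Ko <- params$Ko; Kg <- params$Kg; gam <- params$gamma
  alpha1 <- params$alpha1; alpha2 <- params$alpha2; alpha3 <- params$alpha3
  s <- params$rate_scale
  cns_o <- s * params$beta1 * params$phi_cells * params$Vo * 3600
  cns_g <- s * params$beta2 * params$phi_cells * params$Vg * 3600
  beta2 <- params$beta2
  A1s <- s * params$A1 * 3600
  A2s <- s * params$A2 * 3600
  lam_h <- params$lam * 3600
  vT <- scaffold$v_total
  curv <- env$curvature_fn
  shear <- env$shear_fn

  function(t, y, parms) {
    if (any(!is.finite(y))) {
      stop(sprintf("non-finite state during integration at t = %.3f h", t),
           call. = FALSE)
    }
    if (any(y < -1e-6)) {
      stop(sprintf("state went negative during integration at t = %.3f h", t),
           call. = FALSE)
    }
    y[y < 0] <- 0
    Co <- y[[1L]]; Cg <- y[[2L]]; Cla <- y[[3L]]
    Ve <- y[[4L]]; Vc <- y[[5L]]; gf <- y[[6L]]
    fill <- Vc + Ve
    tau <- shear(fill, flow)
    fs <- if (tau < a1) 0.5 + 0.5 * tau / a1 else
      if (tau < a2) 1 else
        if (tau < a3) (a3 - tau) / (a3 - a2) else 0
    fc <- max(curv(fill), 0)
    h2 <- Cg / (Kg + Cg)
    pH <- 7.4 - 0.0406 * Cla
    h3 <- if (pH >= 7.1) 1 else
      if (pH >= 6.375) 4 / 3 * pH - 8.5 else 0
    P <- fs * fc * (Co / (Ko + Co)) * h2 * h3
    space <- vT - fill
    up_g <- cns_g * fill * h2
    list(c(-cns_o * fill * Co / (Ko + gam * Co),
           -up_g,
           2 / beta2 * up_g,
           A1s * P * Vc * space * alpha1 / (1 + gf),
           A2s * P * Vc * Ve * space * alpha2 * gf / (alpha3 + gf),
           -lam_h * gf))
  }
}

serialize_config_blocks <- function(cfg) {
  drop_fn <- function(x) x[!vapply(x, is.function, logical(1))]
  lapply(cfg, function(block) {
    if (is.list(block)) drop_fn(unclass(block)) else block
  })
}
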