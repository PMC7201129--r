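#' Assemble and validate a full run configuration
#'
#' A run configuration bundles every block the simulator, calibrator and
#' optimizer need: kinetic parameters, scaffold, medium, refreshment
#' regimen, geometry-closure constants, cost model, solver options and
#' seed. Unknown keys are rejected, and every block is validated by its
#' constructor.
#'
#' @param kinetic_parameters,scaffold,medium,regime,environment,cost,solver
#'   Named lists of overrides for the corresponding constructor
#'   ([kinetic_parameters()], [scaffold_spec()], [medium_spec()],
#'   [refreshment_regime()], [environment_model()], [cost_model()],
#'   [solver_options()]); missing fields take the reference defaults.
#' @param seed Integer seed recorded with the run.
#' @param use_reference_scale Apply the stored anchored `rate_scale`
#'   (see [reference_configuration()]) unless the kinetic block sets one
#'   explicitly.
#' @return An object of class `run_config`.
#' @export
run_config <- function(kinetic_parameters = list(),
                       scaffold = list(),
                       medium = list(),
                       regime = list(),
                       environment = list(),
                       cost = list(),
                       solver = list(),
                       seed = 1L,
                       use_reference_scale = TRUE) {
  build <- function(fn, args, block) {
    known <- names(formals(fn))
    bad <- setdiff(names(args), known)
    if (length(bad)) {
      stop(sprintf("unknown key(s) in %s block: %s (known: %s)",
                   block, paste(bad, collapse = ", "),
                   paste(known, collapse = ", ")), call. = FALSE)
    }
    do.call(fn, args)
  }
  if (use_reference_scale && is.null(kinetic_parameters$rate_scale)) {
    kinetic_parameters$rate_scale <-
      reference_configuration()$params$rate_scale
  }
  regime_defaults <- list(period_hours = 48, fraction = 1,
                          duration_days = 28)
  regime <- utils::modifyList(regime_defaults, regime)
  # the block argument shadows the constructor; fetch it from the namespace
  kin_fn <- get("kinetic_parameters", envir = parent.env(environment()))
  cfg <- list(
    params = build(kin_fn, kinetic_parameters, "kinetic_parameters"),
    scaffold = build(scaffold_spec, scaffold, "scaffold"),
    medium = build(medium_spec, medium, "medium"),
    regime = build(refreshment_regime, regime, "regime"),
    env = build(environment_model, environment, "environment"),
    cost = build(cost_model, cost, "cost"),
    solver = build(solver_options, solver, "solver"),
    seed = as.integer(seed)
  )
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration (hash", config_hash(x), ")\n")
  print(x$regime)
  cat(sprintf("  medium: glucose %g, oxygen %g, lactate %g mol/m^3, gf %g ng/ml\n",
              x$medium$glucose0, x$medium$oxygen0, x$medium$lactate0,
              x$medium$gf0))
  cat(sprintf("  rate_scale: %.6g; seed: %d\n", x$params$rate_scale, x$seed))
  invisible(x)
}

#' Load a run configuration from YAML or JSON
#'
#' Reads a configuration file (blocks `kinetic_parameters`, `scaffold`,
#' `medium`, `regime`, `environment`, `cost`, `solver`, `seed`), fills all
#' missing fields from the reference configuration, validates every block
#' and rejects unknown keys. An empty file yields the reference
#' configuration.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  known <- c("kinetic_parameters", "scaffold", "medium", "regime",
             "environment", "cost", "solver", "seed")
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    stop("unknown top-level key(s): ", paste(bad, collapse = ", "),
         " (known: ", paste(known, collapse = ", "), ")", call. = FALSE)
  }
  args <- raw[intersect(names(raw), setdiff(known, "seed"))]
  args <- lapply(args, as.list)
  if (!is.null(raw$seed)) args$seed <- raw$seed
  do.call(run_config, args)
}

#' Save a run configuration to YAML
#'
#' Writes every block's scalar fields; reloading the file with
#' [load_config()] reproduces the configuration exactly.
#'
#' @param config A `run_config`.
#' @param path Output path (`.yaml`).
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(config_as_list(config), path, precision = 15)
  invisible(path)
}

config_as_list <- function(config) {
  list(
    kinetic_parameters = unclass(config$params),
    scaffold = unclass(config$scaffold),
    medium = unclass(config$medium),
    regime = unclass(config$regime),
    cost = unclass(config$cost),
    solver = unclass(config$solver),
    seed = config$seed
  )
}

#' Hash of a run configuration
#'
#' MD5 digest of the canonical YAML serialization; two runs with the same
#' hash and seed are exactly reproducible.
#'
#' @param config A `run_config`.
#' @return A character MD5 string.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config_as_list(config), tmp, precision = 15)
  unname(tools::md5sum(tmp))
}

#' Scenario presets
#'
#' Named culture scenarios used throughout the package:
#' \describe{
#'   \item{`baseline`}{Full exchange every 48 h, 28 days, growth factor at
#'     the 1 ng/ml baseline, perfusion at 0.04 ml/min — the calibration
#'     scenario.}
#'   \item{`koller`}{Static culture (no flow), 50\% exchange every 120 h,
#'     cytokine dose 1.5 ng/ml — a published hematopoietic-cell set-up.}
#'   \item{`eom`}{Full exchange every 55 h under perfusion — a published
#'     growth-factor dose-response set-up.}
#'   \item{`fig_48h_gf1/10/100`, `fig_72h_gf1/10/100`}{The six prediction
#'     scenarios: full exchange every 48 h or 50\% exchange every 72 h, at
#'     1, 10 and 100 times the baseline growth-factor dose.}
#' }
#'
#' @param name Preset name; see [list_presets()].
#' @return A `run_config`.
#' @export
#' @examples
#' scenario_preset("koller")$regime
scenario_preset <- function(name) {
  presets <- preset_table()
  if (!name %in% names(presets)) {
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  }
  do.call(run_config, presets[[name]])
}

preset_table <- function() {
  fig <- function(p, a, gf) {
    list(regime = list(period_hours = p, fraction = a, duration_days = 28),
         medium = list(gf0 = gf))
  }
  list(
    baseline = list(regime = list(period_hours = 48, fraction = 1,
                                  duration_days = 28)),
    koller = list(regime = list(period_hours = 120, fraction = 0.5,
                                duration_days = 28,
                                flow_rate_ml_min = 0),
                  medium = list(gf0 = 1.5)),
    eom = list(regime = list(period_hours = 55, fraction = 1,
                             duration_days = 28)),
    fig_48h_gf1 = fig(48, 1, 1),
    fig_48h_gf10 = fig(48, 1, 10),
    fig_48h_gf100 = fig(48, 1, 100),
    fig_72h_gf1 = fig(72, 0.5, 1),
    fig_72h_gf10 = fig(72, 0.5, 10),
    fig_72h_gf100 = fig(72, 0.5, 100)
  )
}

#' @rdname scenario_preset
#' @export
list_presets <- function() names(preset_table())

#' Run a simulation / calibration / optimization from a configuration
#'
#' High-level entry points binding the modules into reproducible runs;
#' these back the command-line interface. Each writes its outputs under
#' `out_dir` together with the configuration hash and seed.
#'
#' @param config A `run_config` (e.g. from [load_config()] or
#'   [scenario_preset()]).
#' @param out_dir Output directory (created if needed).
#' @param observations An [observation_set()] (for `run_calibrate`).
#' @param fit_params Character vector of parameters to fit.
#' @param bounds_factor Half-width of the fitting box, as a fraction of
#'   each parameter's current value.
#' @param ga A [ga_config()] or `NULL` for defaults.
#' @param mopso A [mopso_config()].
#' @return `run_simulate`: the trajectory; `run_calibrate`: the GA fit;
#'   `run_optimize`: the Pareto front. All invisibly, after writing files.
#' @export
run_simulate <- function(config, out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  traj <- simulate_culture(config$params, config$env, config$scaffold,
                           config$medium, config$regime, config$solver)
  write_trajectory(traj, file.path(out_dir, "trajectory.csv"))
  log_run("simulate", config, t0)
  invisible(traj)
}

#' @rdname run_simulate
#' @export
run_calibrate <- function(config, observations, out_dir = ".",
                          fit_params = c("A1", "A2", "alpha1", "alpha2",
                                         "alpha3"),
                          bounds_factor = 0.5, ga = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  centre <- unlist(unclass(config$params)[fit_params])
  if (is.null(ga)) {
    ga <- ga_config(lower = centre * (1 - bounds_factor),
                    upper = centre * (1 + bounds_factor),
                    seed = config$seed)
  }
  obj <- function(cand) {
    residual_objective(cand, observations, config$params, config$env,
                       config$scaffold, config$medium, config$regime)
  }
  fit <- ga_calibrate(obj, ga)
  out <- list(fitted = as.list(fit$par), objective = fit$value,
              seed = fit$seed, evaluations = fit$evaluations,
              config_hash = config_hash(config))
  jsonlite::write_json(out, file.path(out_dir, "fitted_parameters.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_run("calibrate", config, t0)
  invisible(fit)
}

#' @rdname run_simulate
#' @export
run_optimize <- function(config, out_dir = ".", mopso = mopso_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  ctx <- list(params = config$params, env = config$env,
              scaffold = config$scaffold, medium = config$medium)
  front <- optimize_regimen(ctx, cost = config$cost, mopso = mopso)
  write_pareto_report(front, file.path(out_dir, "pareto.csv"))
  log_run("optimize", config, t0)
  invisible(front)
}

log_run <- function(what, config, t0) {
  message(sprintf("[perfusim] %s: config %s, seed %d, %.2f s elapsed",
                  what, config_hash(config), config$seed,
                  proc.time()[["elapsed"]] - t0))
}
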