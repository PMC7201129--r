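#' Observation set of cell / ECM volume fractions
#'
#' Time-stamped measurements of the cell and ECM volume fractions used for
#' model calibration. Either channel may be missing (`NA`) at any time
#' point; missing values contribute nothing to the fit.
#'
#' @param times Observation times (h), non-negative and sorted.
#' @param cell_fraction Observed cell volume fractions (or `NA`).
#' @param ecm_fraction Observed ECM volume fractions (or `NA`).
#' @param noise_sd Optional named numeric: the noise standard deviation per
#'   channel, recorded as metadata.
#' @param generating_params Optional: the parameters that generated a
#'   synthetic set, recorded as metadata.
#' @return An object of class `observation_set` (a data frame).
#' @export
observation_set <- function(times, cell_fraction = NA_real_,
                            ecm_fraction = NA_real_,
                            noise_sd = NULL, generating_params = NULL) {
  if (any(!is.finite(times)) || any(times < 0) || is.unsorted(times)) {
    stop("observation times must be non-negative and sorted", call. = FALSE)
  }
  obs <- data.frame(time_h = times,
                    cell_fraction = rep_len(cell_fraction, length(times)),
                    ecm_fraction = rep_len(ecm_fraction, length(times)))
  for (ch in c("cell_fraction", "ecm_fraction")) {
    v <- obs[[ch]]
    if (any(v[!is.na(v)] < 0 | v[!is.na(v)] > 1)) {
      stop(ch, " must lie in [0, 1]", call. = FALSE)
    }
  }
  structure(obs, noise_sd = noise_sd, generating_params = generating_params,
            class = c("observation_set", "data.frame"))
}

#' Read / write an observation set
#'
#' CSV with columns `time_h, cell_fraction, ecm_fraction` (empty cells are
#' missing values) plus a JSON metadata sidecar (`<path>.meta.json`).
#'
#' @param obs An [observation_set()].
#' @param path CSV path.
#' @return `path` invisibly; `read_observations` returns the
#'   `observation_set`.
#' @export
write_observations <- function(obs, path) {
  utils::write.csv(as.data.frame(obs), path, row.names = FALSE, na = "")
  meta <- list(noise_sd = attr(obs, "noise_sd"),
               generating_params = attr(obs, "generating_params"))
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  d <- utils::read.csv(path)
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  observation_set(d$time_h, d$cell_fraction, d$ecm_fraction,
                  noise_sd = meta$noise_sd,
                  generating_params = meta$generating_params)
}

#' Generate synthetic observations from known parameters
#'
#' Simulates the culture under `params`, samples the cell and ECM volume
#' fractions at the requested times, and adds independent Gaussian noise
#' (truncated at zero). The generating parameters are recorded in the
#' returned object's metadata, so parameter-recovery experiments are fully
#' self-describing.
#'
#' @param params,env,scaffold,medium,regime Model context as in
#'   [simulate_culture()].
#' @param times Sampling times (h), within the culture duration.
#' @param noise_sd Noise standard deviation, a single value or a named
#'   vector `c(cell = ..., ecm = ...)`.
#' @param seed RNG seed for the noise draws.
#' @param solver A [solver_options()].
#' @param output_dt Output sampling step (h) of the underlying simulation.
#' @return An [observation_set()].
#' @export
synthesize_observations <- function(params = kinetic_parameters(),
                                    env = environment_model(),
                                    scaffold = scaffold_spec(),
                                    medium = medium_spec(),
                                    regime = refreshment_regime(48, 1, 28),
                                    times,
                                    noise_sd = 0,
                                    seed = NULL,
                                    solver = solver_options(),
                                    output_dt = 1) {
  if (any(times < 0) || any(times > regime$duration_days * 24)) {
    stop("sample times must lie within the culture duration", call. = FALSE)
  }
  if (length(noise_sd) == 1L && is.null(names(noise_sd))) {
    noise_sd <- c(cell = unname(noise_sd), ecm = unname(noise_sd))
  }
  traj <- simulate_culture(params, env, scaffold, medium, regime,
                           solver = solver, output_dt = output_dt,
                           extra_times = times)
  # pre-event rows at event times: observations see the culture, not the
  # exchanged medium, and the tissue fractions are continuous anyway
  pre <- traj[traj$event_flag == 0L, ]
  idx <- vapply(times, function(t) which.min(abs(pre$time_h - t)), integer(1))
  cell <- pre$V_cell[idx]
  ecm <- pre$V_ecm[idx]
  if (!is.null(seed)) set.seed(seed)
  if (noise_sd[["cell"]] > 0) {
    cell <- pmax(0, cell + stats::rnorm(length(cell), 0, noise_sd[["cell"]]))
  }
  if (noise_sd[["ecm"]] > 0) {
    ecm <- pmax(0, ecm + stats::rnorm(length(ecm), 0, noise_sd[["ecm"]]))
  }
  observation_set(times, pmin(cell, 1), pmin(ecm, 1),
                  noise_sd = noise_sd,
                  generating_params = unclass(params))
}

#' Calibration objective: normalized sum of squared residuals
#'
#' Simulates the culture with the candidate values substituted into the
#' kinetic parameters and returns the sum, over channels and observation
#' times, of squared differences between simulated and observed volume
#' fractions. Each channel is normalized by the maximum observation of
#' that channel, so the (small) ECM fractions contribute comparably to the
#' cell fractions. Missing observations contribute zero. A failed
#' simulation returns a large finite penalty (1e6) rather than throwing,
#' so population-based optimizers can continue.
#'
#' @param candidate Named numeric vector of fitted parameters; any subset
#'   of the kinetic parameter fields (typically `A1`, `A2`, `alpha1`,
#'   `alpha2`, `alpha3`).
#' @param observations An [observation_set()].
#' @param params,env,scaffold,medium,regime Fixed model context.
#' @param solver A [solver_options()]; calibration usually tolerates a
#'   looser tolerance than reporting runs.
#' @param output_dt Output sampling step (h) for the underlying
#'   simulation; observation times are always sampled.
#' @return Non-negative scalar.
#' @export
residual_objective <- function(candidate, observations,
                               params = kinetic_parameters(),
                               env = environment_model(),
                               scaffold = scaffold_spec(),
                               medium = medium_spec(),
                               regime = refreshment_regime(48, 1, 28),
                               solver = solver_options(),
                               output_dt = 1) {
  p <- unclass(params)
  if (is.null(names(candidate)) || !all(names(candidate) %in% names(p))) {
    stop("candidate must be named with kinetic parameter fields",
         call. = FALSE)
  }
  p[names(candidate)] <- as.list(candidate)
  p <- tryCatch(do.call(kinetic_parameters, p[setdiff(names(p), NULL)]),
                error = function(e) NULL)
  if (is.null(p)) return(1e6)
  sim <- tryCatch(
    simulate_culture(p, env, scaffold, medium, regime, solver = solver,
                     output_dt = output_dt,
                     extra_times = observations$time_h),
    error = function(e) {
      message("simulation failed during calibration: ", conditionMessage(e))
      NULL
    }
  )
  if (is.null(sim)) return(1e6)
  pre <- sim[sim$event_flag == 0L, ]
  idx <- vapply(observations$time_h,
                function(t) which.min(abs(pre$time_h - t)), integer(1))
  total <- 0
  for (ch in c("cell", "ecm")) {
    obs <- observations[[paste0(ch, "_fraction")]]
    mod <- if (ch == "cell") pre$V_cell[idx] else pre$V_ecm[idx]
    keep <- !is.na(obs)
    if (!any(keep)) next
    scale <- max(obs[keep])
    if (scale <= 0) scale <- 1
    total <- total + sum(((mod[keep] - obs[keep]) / scale)^2)
  }
  total
}

#' Genetic-algorithm configuration
#'
#' Hyper-parameters of the real-coded genetic algorithm used for
#' calibration: tournament selection, blend (BLX-alpha) crossover,
#' Gaussian mutation and single-individual elitism.
#'
#' @param lower,upper Named numeric vectors of parameter bounds
#'   (finite, `lower < upper`), one entry per fitted parameter.
#' @param pop_size Population size (>= 2).
#' @param generations Number of generations.
#' @param crossover_rate Probability a pair is recombined.
#' @param mutation_rate Per-gene mutation probability.
#' @param mutation_scale Mutation standard deviation as a fraction of each
#'   bound width.
#' @param tournament_k Tournament size for parent selection.
#' @param blend_alpha Expansion factor of the blend crossover interval.
#' @param elitism Number of best individuals copied unchanged.
#' @param seed RNG seed.
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(lower, upper,
                      pop_size = 50, generations = 100,
                      crossover_rate = 0.9,
                      mutation_rate = 0.1, mutation_scale = 0.1,
                      tournament_k = 3, blend_alpha = 0.5,
                      elitism = 1, seed = 1) {
  if (is.null(names(lower)) || !identical(names(lower), names(upper))) {
    stop("lower and upper must be named identically", call. = FALSE)
  }
  if (any(!is.finite(lower)) || any(!is.finite(upper)) ||
      any(lower >= upper)) {
    stop("bounds must be finite with lower < upper", call. = FALSE)
  }
  if (pop_size < 2) stop("population size must be >= 2", call. = FALSE)
  structure(
    list(lower = lower, upper = upper, pop_size = pop_size,
         generations = generations, crossover_rate = crossover_rate,
         mutation_rate = mutation_rate, mutation_scale = mutation_scale,
         tournament_k = tournament_k, blend_alpha = blend_alpha,
         elitism = elitism, seed = seed,
         selection = "tournament"),
    class = "ga_config"
  )
}

#' Calibrate parameters with a real-coded genetic algorithm
#'
#' Minimizes `objective` over the box defined by the configuration bounds.
#' Deterministic given the configured seed; with elitism >= 1 the
#' best-objective trace is non-increasing across generations.
#'
#' @param objective Function of a named numeric vector (one entry per
#'   bound) returning a non-negative scalar to minimize.
#' @param config A [ga_config()].
#' @return A list with `par` (best candidate, named), `value` (its
#'   objective), `trace` (best objective per generation), `seed`, and
#'   `evaluations`.
#' @export
#' @examples
#' sphere <- function(x) sum((x - 2)^2)
#' fit <- ga_calibrate(sphere, ga_config(c(a = -5, b = -5), c(a = 5, b = 5),
#'                                       pop_size = 30, generations = 40))
#' fit$par
ga_calibrate <- function(objective, config) {
  stopifnot(inherits(config, "ga_config"))
  lower <- config$lower; upper <- config$upper
  d <- length(lower)
  width <- upper - lower
  if (!is.null(config$seed)) set.seed(config$seed)

  n <- config$pop_size
  pop <- matrix(stats::runif(n * d, rep(lower, each = n), rep(upper, each = n)),
                nrow = n, ncol = d, dimnames = list(NULL, names(lower)))
  evals <- 0L
  score <- apply(pop, 1L, function(x) objective(stats::setNames(x, names(lower))))
  evals <- evals + n
  if (all(!is.finite(score))) {
    stop("all initial candidates infeasible: objective returned no finite value",
         call. = FALSE)
  }
  trace <- numeric(config$generations)

  tournament <- function() {
    idx <- sample.int(n, config$tournament_k, replace = TRUE)
    idx[which.min(score[idx])]
  }

  for (g in seq_len(config$generations)) {
    ord <- order(score)
    elite <- pop[ord[seq_len(config$elitism)], , drop = FALSE]
    elite_score <- score[ord[seq_len(config$elitism)]]

    children <- matrix(NA_real_, n, d, dimnames = list(NULL, names(lower)))
    i <- 1L
    while (i <= n) {
      p1 <- pop[tournament(), ]; p2 <- pop[tournament(), ]
      if (stats::runif(1) < config$crossover_rate) {
        u <- stats::runif(d, -config$blend_alpha, 1 + config$blend_alpha)
        c1 <- u * p1 + (1 - u) * p2
        c2 <- (1 - u) * p1 + u * p2
      } else {
        c1 <- p1; c2 <- p2
      }
      children[i, ] <- c1
      if (i + 1L <= n) children[i + 1L, ] <- c2
      i <- i + 2L
    }
    mut <- matrix(stats::runif(n * d) < config$mutation_rate, n, d)
    noise <- matrix(stats::rnorm(n * d, 0, rep(config$mutation_scale * width,
                                               each = n)), n, d)
    children[mut] <- children[mut] + noise[mut]
    children <- pmin(pmax(children, rep(lower, each = n)),
                     rep(upper, each = n))

    child_score <- apply(children, 1L,
                         function(x) objective(stats::setNames(x, names(lower))))
    evals <- evals + n
    # elitism: overwrite the worst children with the parents' best
    worst <- order(child_score, decreasing = TRUE)[seq_len(config$elitism)]
    children[worst, ] <- elite
    child_score[worst] <- elite_score
    pop <- children
    score <- child_score
    trace[g] <- min(score)
  }

  best <- which.min(score)
  list(par = stats::setNames(pop[best, ], names(lower)),
       value = score[best], trace = trace,
       seed = config$seed, evaluations = evals)
}
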