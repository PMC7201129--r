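#' Experiment cost model
#'
#' Per-exchange consumable and labor prices for one bioreactor circuit.
#' The total cost of a culture under regimen `(p, a)` with initial
#' growth-factor dose `gf0` is
#' \deqn{C = (M + gf0 \cdot Pg) (1 + \frac{24 d}{p} a) + L (1 + \frac{24 d}{p})}
#' where `24 d / p` is the number of refreshments over `d` days: medium and
#' growth-factor use scale with the exchanged fraction `a`, labor does
#' not, and the `+1` terms are the initial fill and set-up labor.
#'
#' @param medium_cost_per_exchange Cost M of the medium for one full
#'   exchange (EUR); default 0.2611.
#' @param labor_cost_per_exchange Labor cost L of one refreshment (EUR);
#'   default 6.8.
#' @param gf_price_per_ng_ml Price Pg of the growth factor per ng/ml dose
#'   in one 10 ml reservoir (EUR). Not a published number; the default
#'   0.362 is back-solved from the two published (regimen, cost) pairs.
#' @param duration_days Culture duration d (days).
#' @return An object of class `cost_model`.
#' @export
cost_model <- function(medium_cost_per_exchange = 0.2611,
                       labor_cost_per_exchange = 6.8,
                       gf_price_per_ng_ml = 0.362,
                       duration_days = 28) {
  vals <- c(medium_cost_per_exchange, labor_cost_per_exchange,
            gf_price_per_ng_ml, duration_days)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("cost model fields must be finite and >= 0", call. = FALSE)
  }
  structure(list(medium_cost_per_exchange = medium_cost_per_exchange,
                 labor_cost_per_exchange = labor_cost_per_exchange,
                 gf_price_per_ng_ml = gf_price_per_ng_ml,
                 duration_days = duration_days),
            class = "cost_model")
}

#' Total cost of a culture regimen
#'
#' Evaluates the cost model (see [cost_model()]) for a decision vector
#' (refreshment period, exchanged fraction, growth-factor dose).
#'
#' @param period_hours Refreshment period p (h), > 0.
#' @param fraction Exchanged fraction a, in `[0, 1]`.
#' @param gf0 Initial growth-factor dose (ng/ml; multiples of the 1 ng/ml
#'   baseline).
#' @param cost A [cost_model()].
#' @return Total cost in EUR. Vectorized over the decision arguments.
#' @export
#' @examples
#' experiment_cost(48, 1, 0)   # baseline regimen, no growth factor
#' experiment_cost(12, 0.65, 7)  # the sweet-spot regimen
experiment_cost <- function(period_hours, fraction, gf0 = 0,
                            cost = cost_model()) {
  if (any(!is.finite(period_hours)) || any(period_hours <= 0)) {
    stop("period_hours must be > 0", call. = FALSE)
  }
  if (any(fraction < 0) || any(fraction > 1)) {
    stop("fraction must lie in [0, 1]", call. = FALSE)
  }
  if (any(gf0 < 0)) stop("gf0 must be >= 0", call. = FALSE)
  n <- 24 * cost$duration_days / period_hours
  (cost$medium_cost_per_exchange + gf0 * cost$gf_price_per_ng_ml) *
    (1 + n * fraction) +
    cost$labor_cost_per_exchange * (1 + n)
}

#' Pareto dominance between two candidate regimens
#'
#' `a` dominates `b` when it is at least as good in both objectives
#' (cell volume to maximize, cost to minimize) and strictly better in at
#' least one.
#'
#' @param a,b Lists or one-row data frames with elements `cell` (final
#'   cell volume fraction) and `cost` (EUR).
#' @return Logical.
#' @export
dominates <- function(a, b) {
  (a$cell >= b$cell && a$cost <= b$cost) &&
    (a$cell > b$cell || a$cost < b$cost)
}

#' Non-dominated (Pareto) subset of candidate points
#'
#' Returns the maximal subset of mutually non-dominated points, ordered by
#' cost ascending. Duplicated objective pairs are kept once.
#'
#' @param points Data frame with numeric columns `cell` (maximize) and
#'   `cost` (minimize); other columns are carried through.
#' @return The non-dominated rows of `points`, cost-ascending.
#' @export
pareto_front <- function(points) {
  if (!is.data.frame(points) || nrow(points) == 0) {
    stop("points must be a non-empty data frame", call. = FALSE)
  }
  stopifnot(all(c("cell", "cost") %in% names(points)))
  pts <- points[!duplicated(points[, c("cell", "cost")]), , drop = FALSE]
  ord <- order(pts$cost, -pts$cell)
  pts <- pts[ord, , drop = FALSE]
  # after cost-ascending sort, a point is non-dominated iff its cell value
  # strictly exceeds every cheaper point's
  best <- cummax(c(-Inf, pts$cell[-nrow(pts)]))
  keep <- pts$cell > best
  out <- pts[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Knee (sweet-spot) point of a Pareto front
#'
#' After min-max normalization of both objectives, returns the front point
#' with maximum perpendicular distance from the straight segment joining
#' the two extremes (cheapest and most expensive point). For fronts with
#' fewer than three points the cheapest point is returned with a warning;
#' a collinear front is flagged degenerate (attribute `degenerate`).
#'
#' @param front Data frame as returned by [pareto_front()].
#' @return One row of `front`, with attributes `knee_distance` and
#'   `degenerate`.
#' @export
knee_point <- function(front) {
  stopifnot(is.data.frame(front), all(c("cell", "cost") %in% names(front)))
  if (nrow(front) < 3) {
    warning("front has fewer than 3 points; returning the cheapest",
            call. = FALSE)
    out <- front[which.min(front$cost), , drop = FALSE]
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  # normalize both objectives to [0,1]; work in minimize-minimize space
  f1 <- -front$cell
  f2 <- front$cost
  norm01 <- function(x) {
    r <- range(x)
    if (diff(r) == 0) rep(0, length(x)) else (x - r[1]) / diff(r)
  }
  x <- norm01(f2); y <- norm01(f1)
  i1 <- which.min(front$cost); i2 <- which.max(front$cost)
  p1 <- c(x[i1], y[i1]); p2 <- c(x[i2], y[i2])
  seg <- p2 - p1
  len <- sqrt(sum(seg^2))
  if (len == 0) {
    d <- rep(0, nrow(front))
  } else {
    d <- abs(seg[2] * (x - p1[1]) - seg[1] * (y - p1[2])) / len
  }
  degenerate <- max(d) < 1e-12
  out <- front[which.max(d), , drop = FALSE]
  attr(out, "knee_distance") <- max(d)
  attr(out, "degenerate") <- degenerate
  out
}

#' Multi-objective particle swarm optimizer configuration
#'
#' @param swarm_size Number of particles.
#' @param iterations Number of velocity/position updates.
#' @param inertia Inertia weight w.
#' @param cognitive,social Acceleration coefficients c1, c2.
#' @param velocity_clamp Maximum speed per dimension as a fraction of the
#'   bound width.
#' @param archive_cap Maximum external-archive size (crowding-distance
#'   truncation beyond it).
#' @param seed RNG seed.
#' @return An object of class `mopso_config`.
#' @export
mopso_config <- function(swarm_size = 100, iterations = 50,
                         inertia = 0.7, cognitive = 1.5, social = 1.5,
                         velocity_clamp = 0.2, archive_cap = 100,
                         seed = 1) {
  stopifnot(swarm_size >= 2, iterations >= 1)
  structure(list(swarm_size = swarm_size, iterations = iterations,
                 inertia = inertia, cognitive = cognitive, social = social,
                 velocity_clamp = velocity_clamp, archive_cap = archive_cap,
                 seed = seed),
            class = "mopso_config")
}

# crowding distance of rows of a 2-column objective matrix (min-min space)
crowding_distance <- function(obj) {
  n <- nrow(obj)
  if (n <= 2) return(rep(Inf, n))
  d <- rep(0, n)
  for (j in seq_len(ncol(obj))) {
    ord <- order(obj[, j])
    rng <- obj[ord[n], j] - obj[ord[1], j]
    d[ord[c(1, n)]] <- Inf
    if (rng > 0) {
      d[ord[2:(n - 1)]] <- d[ord[2:(n - 1)]] +
        (obj[ord[3:n], j] - obj[ord[1:(n - 2)], j]) / rng
    }
  }
  d
}

# non-dominated filter in minimize-minimize space; returns logical index
nondominated_min <- function(obj) {
  n <- nrow(obj)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    if (!keep[i]) next
    dominated <- obj[, 1] <= obj[i, 1] & obj[, 2] <= obj[i, 2] &
      (obj[, 1] < obj[i, 1] | obj[, 2] < obj[i, 2])
    if (any(dominated & keep)) keep[i] <- FALSE
  }
  keep
}

#' Multi-objective particle swarm optimization (external archive)
#'
#' Archive-based MOPSO over a box-bounded decision space for two
#' objectives, both minimized: an external archive keeps the non-dominated
#' solutions found so far; leaders are drawn from the archive by binary
#' tournament on crowding distance (preferring sparse regions); the
#' archive is truncated to its cap by discarding the most crowded
#' members. Velocities are clamped per dimension and positions reflect at
#' the bounds. Deterministic given the configured seed.
#'
#' @param evaluate Function mapping a decision vector (named numeric) to a
#'   numeric vector of two objective values, both to be minimized.
#' @param lower,upper Named bound vectors (finite, `lower < upper`).
#' @param config A [mopso_config()].
#' @return A data frame: decision columns, objective columns `f1`, `f2`;
#'   every row non-dominated within all evaluated points.
#' @export
#' @examples
#' toy <- function(x) c(x[["x"]]^2, (x[["x"]] - 2)^2)
#' arch <- mopso_optimize(toy, c(x = -5), c(x = 5),
#'                        mopso_config(swarm_size = 30, iterations = 30))
#' range(arch$x)  # spans the trade-off segment [0, 2]
mopso_optimize <- function(evaluate, lower, upper, config = mopso_config()) {
  if (is.null(names(lower)) || !identical(names(lower), names(upper))) {
    stop("lower and upper must be named identically", call. = FALSE)
  }
  if (any(!is.finite(lower)) || any(!is.finite(upper)) ||
      any(lower >= upper)) {
    stop("infeasible bounds: need finite lower < upper", call. = FALSE)
  }
  d <- length(lower)
  width <- upper - lower
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$swarm_size

  eval_named <- function(x) evaluate(stats::setNames(x, names(lower)))
  X <- matrix(stats::runif(n * d, rep(lower, each = n), rep(upper, each = n)),
              n, d, dimnames = list(NULL, names(lower)))
  V <- matrix(0, n, d)
  Fobj <- t(apply(X, 1L, eval_named))
  pbest_x <- X
  pbest_f <- Fobj

  arch_x <- X[nondominated_min(Fobj), , drop = FALSE]
  arch_f <- Fobj[nondominated_min(Fobj), , drop = FALSE]

  truncate_archive <- function() {
    if (nrow(arch_x) > config$archive_cap) {
      cd <- crowding_distance(arch_f)
      keep <- order(cd, decreasing = TRUE)[seq_len(config$archive_cap)]
      arch_x <<- arch_x[keep, , drop = FALSE]
      arch_f <<- arch_f[keep, , drop = FALSE]
    }
  }
  truncate_archive()

  pick_leader <- function() {
    m <- nrow(arch_x)
    if (m == 1) return(1L)
    cd <- crowding_distance(arch_f)
    cand <- sample.int(m, 2L, replace = TRUE)
    cand[which.max(cd[cand])]
  }

  vmax <- config$velocity_clamp * width
  for (it in seq_len(config$iterations)) {
    cd_cache <- NULL
    for (i in seq_len(n)) {
      lead <- arch_x[pick_leader(), ]
      r1 <- stats::runif(d); r2 <- stats::runif(d)
      V[i, ] <- config$inertia * V[i, ] +
        config$cognitive * r1 * (pbest_x[i, ] - X[i, ]) +
        config$social * r2 * (lead - X[i, ])
      V[i, ] <- pmin(pmax(V[i, ], -vmax), vmax)
      xi <- X[i, ] + V[i, ]
      # reflect at the bounds
      below <- xi < lower; above <- xi > upper
      xi[below] <- lower[below] + (lower[below] - xi[below])
      xi[above] <- upper[above] - (xi[above] - upper[above])
      xi <- pmin(pmax(xi, lower), upper)
      V[i, below | above] <- -V[i, below | above]
      X[i, ] <- xi
    }
    Fobj <- t(apply(X, 1L, eval_named))
    for (i in seq_len(n)) {
      # personal best: replace when the new point dominates, or on a coin
      # flip when mutually non-dominated
      new_dom <- all(Fobj[i, ] <= pbest_f[i, ]) && any(Fobj[i, ] < pbest_f[i, ])
      old_dom <- all(pbest_f[i, ] <= Fobj[i, ]) && any(pbest_f[i, ] < Fobj[i, ])
      if (new_dom || (!old_dom && stats::runif(1) < 0.5)) {
        pbest_x[i, ] <- X[i, ]
        pbest_f[i, ] <- Fobj[i, ]
      }
    }
    arch_x <- rbind(arch_x, X)
    arch_f <- rbind(arch_f, Fobj)
    keep <- nondominated_min(arch_f)
    dup <- duplicated(cbind(arch_f, arch_x))
    keep <- keep & !dup
    arch_x <- arch_x[keep, , drop = FALSE]
    arch_f <- arch_f[keep, , drop = FALSE]
    truncate_archive()
  }

  out <- as.data.frame(arch_x)
  out$f1 <- arch_f[, 1]
  out$f2 <- arch_f[, 2]
  out[order(out$f2), , drop = FALSE]
}

#' Optimize a culture regimen for cell yield versus cost
#'
#' Runs the multi-objective PSO over (refreshment period, exchanged
#' fraction, growth-factor dose), evaluating each candidate by a full
#' culture simulation under the supplied configuration: objective one is
#' the final cell volume fraction (maximized), objective two the total
#' experiment cost (minimized).
#'
#' @param config Model context as from [reference_configuration()].
#' @param cost A [cost_model()]; its duration is used for the simulated
#'   cultures.
#' @param lower,upper Decision bounds, named `period_hours`, `fraction`,
#'   `gf0`. Defaults: period 4-96 h, fraction 0.05-1, dose 1-100 ng/ml.
#' @param mopso A [mopso_config()].
#' @return A data frame of Pareto-optimal regimens with columns
#'   `period_hours`, `fraction`, `gf0`, `final_cell_fraction`,
#'   `final_cell_count`, `cost_eur`, `is_knee`, cost-ascending.
#' @export
optimize_regimen <- function(config = reference_configuration(),
                             cost = cost_model(),
                             lower = c(period_hours = 4, fraction = 0.05, gf0 = 1),
                             upper = c(period_hours = 96, fraction = 1, gf0 = 100),
                             mopso = mopso_config()) {
  evaluate <- function(x) {
    regime <- refreshment_regime(x[["period_hours"]], x[["fraction"]],
                                 cost$duration_days)
    medium <- medium_spec(gf0 = x[["gf0"]] * config$medium$gf0)
    traj <- tryCatch(
      simulate_culture(config$params, config$env, config$scaffold,
                       medium, regime, output_dt = 24),
      error = function(e) NULL
    )
    final_cell <- if (is.null(traj)) 0 else traj$V_cell[nrow(traj)]
    c(-final_cell,
      experiment_cost(x[["period_hours"]], x[["fraction"]], x[["gf0"]], cost))
  }
  arch <- mopso_optimize(evaluate, lower, upper, mopso)
  front <- data.frame(period_hours = arch$period_hours,
                      fraction = arch$fraction,
                      gf0 = arch$gf0,
                      cell = -arch$f1,
                      cost = arch$f2)
  front <- pareto_front(front)
  front$final_cell_fraction <- front$cell
  front$final_cell_count <- cells_from_fraction(front$cell, config$scaffold)
  front$cost_eur <- front$cost
  front$is_knee <- FALSE
  if (nrow(front) >= 3) {
    knee <- knee_point(front)
    front$is_knee <- seq_len(nrow(front)) == as.integer(rownames(knee))
  }
  front[, c("period_hours", "fraction", "gf0", "final_cell_fraction",
            "final_cell_count", "cost_eur", "is_knee")]
}

#' Write a Pareto report
#'
#' CSV with columns `p_hours, fraction, gf0, final_cell_fraction,
#' final_cell_count, cost_eur, is_knee`.
#'
#' @param front Data frame from [optimize_regimen()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_pareto_report <- function(front, path) {
  out <- data.frame(p_hours = front$period_hours,
                    fraction = front$fraction,
                    gf0 = front$gf0,
                    final_cell_fraction = front$final_cell_fraction,
                    final_cell_count = front$final_cell_count,
                    cost_eur = front$cost_eur,
                    is_knee = front$is_knee)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
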