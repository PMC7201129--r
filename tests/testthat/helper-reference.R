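# shared fixtures, built once per test run

# anchored reference configuration (read from the versioned fixture)
ref_config <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- reference_configuration()
    cache
  }
})

# fast solver settings for calibration-scale fixtures
fast_solver <- function() solver_options(rtol = 1e-6, atol = 1e-9)

# brute-force fixed-step classical Runge-Kutta integration of the culture
# model, independent of deSolve; dt in seconds, window in hours. Returns
# the state sampled every `sample_h` hours (including t = 0).
rk4_culture <- function(state, params, env, scaffold, flow,
                        window_h, dt_s = 1, sample_h = 1) {
  f <- function(y) state_derivative(y, params, env, scaffold,
                                    flow_rate_ml_min = flow)
  n_per_sample <- round(sample_h * 3600 / dt_s)
  n_samples <- round(window_h / sample_h)
  out <- matrix(NA_real_, n_samples + 1L, length(state),
                dimnames = list(NULL, names(state)))
  out[1L, ] <- state
  y <- state
  for (i in seq_len(n_samples)) {
    for (k in seq_len(n_per_sample)) {
      k1 <- f(y)
      k2 <- f(y + dt_s / 2 * k1)
      k3 <- f(y + dt_s / 2 * k2)
      k4 <- f(y + dt_s * k3)
      y <- y + dt_s / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    out[i + 1L, ] <- y
  }
  data.frame(time_h = seq(0, window_h, by = sample_h), out)
}

# O(n^2) pairwise-dominance oracle for the Pareto front
brute_force_front <- function(points) {
  n <- nrow(points)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && dominates(points[j, ], points[i, ])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  out <- points[keep, , drop = FALSE]
  out <- out[order(out$cost), , drop = FALSE]
  rownames(out) <- NULL
  out
}
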