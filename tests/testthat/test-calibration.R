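# shared fast fixture: a synthetic truth with brisker dynamics than the
# anchored reference so that a 4-day culture already carries a clear
# growth signal (final cell fraction about 6x the seeded value)
cal_truth <- kinetic_parameters(rate_scale = 3e-11)
cal_regime <- refreshment_regime(24, 1, 4)
cal_medium <- medium_spec(gf0 = 5)
cal_times <- seq(12, 96, by = 12)
cal_solver <- solver_options(rtol = 1e-5, atol = 1e-8)
cal_names <- c("A1", "A2", "alpha1", "alpha2", "alpha3")
cal_centre <- unlist(unclass(cal_truth)[cal_names])

cal_objective <- function(obs) {
  function(cand) {
    residual_objective(cand, obs, params = cal_truth, medium = cal_medium,
                       regime = cal_regime, solver = cal_solver,
                       output_dt = 96)
  }
}

test_that("synthetic observations reproduce the simulator exactly at zero noise", {
  obs <- synthesize_observations(cal_truth, regime = cal_regime,
                                 medium = cal_medium,
                                 times = c(0, 48, 96), noise_sd = 0)
  expect_equal(obs$cell_fraction[1], 0.0139)
  expect_equal(obs$ecm_fraction[1], 0)
  traj <- simulate_culture(cal_truth, medium = cal_medium,
                           regime = cal_regime)
  pre <- traj[traj$event_flag == 0L, ]
  for (k in 2:3) {
    row <- pre[pre$time_h == obs$time_h[k], ]
    expect_equal(obs$cell_fraction[k], row$V_cell)
    expect_equal(obs$ecm_fraction[k], row$V_ecm)
  }
  expect_equal(attr(obs, "generating_params")$rate_scale, 3e-11)
})

test_that("noisy observation means converge to the noiseless signal", {
  noiseless <- synthesize_observations(cal_truth, regime = cal_regime,
                                       medium = cal_medium,
                                       times = c(48, 96), noise_sd = 0,
                                       solver = cal_solver, output_dt = 48)
  sd <- 0.005
  n <- 60
  draws <- vapply(seq_len(n), function(s) {
    synthesize_observations(cal_truth, regime = cal_regime,
                            medium = cal_medium, times = c(48, 96),
                            noise_sd = sd, seed = s,
                            solver = cal_solver, output_dt = 48)$cell_fraction
  }, numeric(2))
  means <- rowMeans(draws)
  expect_true(all(abs(means - noiseless$cell_fraction) <= 3 * sd / sqrt(n)))
})

test_that("observation sets round-trip through CSV with metadata", {
  obs <- synthesize_observations(cal_truth, regime = cal_regime,
                                 medium = cal_medium,
                                 times = c(0, 48, 96), noise_sd = 0.002,
                                 seed = 9, solver = cal_solver,
                                 output_dt = 48)
  path <- withr::local_tempfile(fileext = ".csv")
  write_observations(obs, path)
  back <- read_observations(path)
  expect_equal(back$cell_fraction, obs$cell_fraction)
  expect_equal(back$ecm_fraction, obs$ecm_fraction)
  expect_equal(attr(back, "generating_params")$A2, 5.612e12)
})

test_that("the residual objective matches a hand-summed oracle on a 3-point fixture", {
  traj <- simulate_culture(cal_truth, medium = cal_medium,
                           regime = cal_regime, extra_times = c(30, 60, 90))
  pre <- traj[traj$event_flag == 0L, ]
  sim_cell <- sapply(c(30, 60, 90), function(t) pre$V_cell[pre$time_h == t])
  sim_ecm <- sapply(c(30, 60, 90), function(t) pre$V_ecm[pre$time_h == t])

  obs_cell <- c(0.016, 0.025, NA)          # one missing cell observation
  obs_ecm <- c(2e-8, 3e-8, 5e-8)
  obs <- observation_set(c(30, 60, 90), obs_cell, obs_ecm)

  # brute-force oracle: plain arithmetic, channel-wise max normalization
  oracle <- sum(((sim_cell[1:2] - obs_cell[1:2]) / max(obs_cell, na.rm = TRUE))^2) +
    sum(((sim_ecm - obs_ecm) / max(obs_ecm))^2)

  got <- residual_objective(stats::setNames(cal_centre, cal_names), obs,
                            params = cal_truth, medium = cal_medium,
                            regime = cal_regime)
  expect_equal(got, oracle, tolerance = 1e-6)
})

test_that("the objective is zero at the generating parameters and positive away from them", {
  obs <- synthesize_observations(cal_truth, regime = cal_regime,
                                 medium = cal_medium, times = cal_times,
                                 noise_sd = 0)
  obj <- cal_objective(obs)
  expect_lt(obj(cal_centre), 1e-6)
  doubled <- replace(cal_centre, "A2", cal_centre[["A2"]] * 2)
  expect_gt(obj(doubled), 1)
})

test_that("the genetic algorithm minimizes a shifted 5-D sphere to its optimum", {
  centre <- c(a = 1.2, b = -3.4, c = 0.5, d = 4.4, e = -2.2)
  sphere <- function(x) sum((x - centre)^2)
  cfg <- ga_config(lower = stats::setNames(rep(-5, 5), names(centre)),
                   upper = stats::setNames(rep(5, 5), names(centre)),
                   pop_size = 50, generations = 100, seed = 7)
  fit <- ga_calibrate(sphere, cfg)
  # within 1% of the search range of the known optimum, per coordinate
  expect_true(all(abs(fit$par - centre) < 0.1))
  expect_lt(fit$value, 0.01)
  # elitism: the best objective never deteriorates across generations
  expect_true(all(diff(fit$trace) <= 0))
})

test_that("the genetic algorithm is reproducible from its seed", {
  sphere <- function(x) sum((x - 1)^2)
  cfg <- ga_config(c(x = -5, y = -5), c(x = 5, y = 5),
                   pop_size = 20, generations = 15, seed = 123)
  f1 <- ga_calibrate(sphere, cfg)
  f2 <- ga_calibrate(sphere, cfg)
  expect_identical(f1$par, f2$par)
  expect_identical(f1$trace, f2$trace)
})

test_that("zero-noise observations allow parameter recovery within tight bounds", {
  obs <- synthesize_observations(cal_truth, regime = cal_regime,
                                 medium = cal_medium, times = cal_times,
                                 noise_sd = 0)
  fit <- ga_calibrate(cal_objective(obs),
                      ga_config(cal_centre * 0.9, cal_centre * 1.1,
                                pop_size = 24, generations = 30, seed = 42))
  rel <- abs(fit$par - cal_centre) / cal_centre
  expect_true(all(rel <= 0.10))
  # the ECM and proliferation scales enter the dynamics as the products
  # A1*alpha1 and A2*alpha2; those combinations (and the half-saturation
  # dose) are what the data identify
  p <- fit$par
  expect_lt(abs(p[["A1"]] * p[["alpha1"]] /
                  (cal_centre[["A1"]] * cal_centre[["alpha1"]]) - 1), 0.10)
  expect_lt(abs(p[["A2"]] * p[["alpha2"]] /
                  (cal_centre[["A2"]] * cal_centre[["alpha2"]]) - 1), 0.10)
  expect_lt(abs(p[["alpha3"]] / cal_centre[["alpha3"]] - 1), 0.10)
  expect_lt(fit$value, 0.01)
})

test_that("recovery error grows with observation noise in expectation", {
  recover_err <- function(noise, seed) {
    obs <- synthesize_observations(cal_truth, regime = cal_regime,
                                   medium = cal_medium, times = cal_times,
                                   noise_sd = noise, seed = seed,
                                   solver = cal_solver, output_dt = 96)
    fit <- ga_calibrate(cal_objective(obs),
                        ga_config(cal_centre * 0.9, cal_centre * 1.1,
                                  pop_size = 10, generations = 6,
                                  seed = seed))
    p <- fit$par
    mean(abs(c(
      p[["A1"]] * p[["alpha1"]] / (cal_centre[["A1"]] * cal_centre[["alpha1"]]) - 1,
      p[["A2"]] * p[["alpha2"]] / (cal_centre[["A2"]] * cal_centre[["alpha2"]]) - 1,
      p[["alpha3"]] / cal_centre[["alpha3"]] - 1
    )))
  }
  seeds <- 1:10
  mean_err <- vapply(c(0, 0.004, 0.02), function(noise) {
    mean(vapply(seeds, function(s) recover_err(noise, s), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_err) > 0))
})

test_that("anchoring the rate scales reproduces the anchor and is monotone", {
  ref <- ref_config()

  # direct oracle: the end-of-culture count increases with the multiplier
  day28 <- vapply(c(0.5, 1, 2), function(m) {
    p <- kinetic_parameters(rate_scale = ref$params$rate_scale * m)
    traj <- simulate_culture(p, output_dt = 48)
    traj$cells[nrow(traj)]
  }, numeric(1))
  expect_true(all(diff(day28) > 0))

  # fixed point: anchoring to the model's own output returns multiplier 1
  fix <- normalize_reference_configuration(anchor_cells = day28[2],
                                           params = ref$params)
  expect_equal(fix$multiplier, 1, tolerance = 1e-3)

  # a larger anchor requires a larger multiplier
  m_lo <- normalize_reference_configuration(anchor_cells = 4e5,
                                            params = ref$params)$multiplier
  m_hi <- normalize_reference_configuration(anchor_cells = 8e5,
                                            params = ref$params)$multiplier
  expect_lt(m_lo, m_hi)

  # infeasible anchors fail loudly
  expect_error(normalize_reference_configuration(anchor_cells = 5e4),
               "exceed the seeded")
})

test_that("the stored reference configuration reproduces the published anchor", {
  ref <- ref_config()
  traj <- simulate_culture(ref$params, regime = ref$regime, output_dt = 48)
  expect_equal(traj$cells[nrow(traj)], 6.9e5, tolerance = 1e-3)
})
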