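test_that("medium refreshment is a percentage-weighted average that spares oxygen", {
  med <- medium_spec()
  st <- culture_state(Co = 0.11, Cg = 5, Cla = 12, V_ecm = 0.02,
                      V_cell = 0.08, gf = 0.3)

  full <- apply_refreshment(st, med, 1)
  expect_equal(full[["Cg"]], 25)
  expect_equal(full[["Cla"]], 0)
  expect_equal(full[["gf"]], med$gf0)
  expect_equal(full[["Co"]], 0.11)
  expect_equal(full[["V_cell"]], 0.08)
  expect_equal(full[["V_ecm"]], 0.02)

  expect_equal(apply_refreshment(st, med, 0), st)
  half <- apply_refreshment(st, med, 0.5)
  expect_equal(half[["Cg"]], 15)
  expect_equal(half[["Cla"]], 6)

  expect_error(apply_refreshment(st, med, 1.2), "\\[0, 1\\]")
  expect_error(apply_refreshment(st, med, -0.1), "\\[0, 1\\]")
})

test_that("cell count conversion is pinned to the seeding condition", {
  sc <- scaffold_spec()
  expect_equal(cells_from_fraction(0.0139, sc), 1e5)
  expect_equal(cells_from_fraction(0, sc), 0)
  expect_equal(cells_from_fraction(0.0959, sc), 6.9e5, tolerance = 1e-3)
  x <- stats::runif(20, 0, 1)
  expect_equal(fraction_from_cells(cells_from_fraction(x, sc), sc), x)
})

test_that("switching growth off leaves the seeded tissue untouched", {
  ref <- ref_config()
  p0 <- kinetic_parameters(A1 = 0, A2 = 0, rate_scale = ref$params$rate_scale)
  traj <- simulate_culture(p0, regime = refreshment_regime(48, 1, 4))
  expect_true(all(abs(traj$V_cell - 0.0139) < 1e-12))
  expect_true(all(traj$V_ecm == 0))
})

test_that("trajectory starts from the seeding state and restores glucose at full exchanges", {
  ref <- ref_config()
  traj <- simulate_culture(ref$params, regime = refreshment_regime(48, 1, 8))
  first <- traj[1, ]
  expect_equal(first$time_h, 0)
  expect_equal(first$V_cell, 0.0139)
  expect_equal(first$V_ecm, 0)
  expect_equal(first$Cg, 25)
  expect_equal(first$Co, 0.192)
  expect_equal(first$Cla, 0)
  expect_equal(first$pH, 7.4)

  post <- traj[traj$event_flag == 1L, ]
  expect_identical(nrow(post), 3L)
  expect_true(all(post$Cg == 25))
  expect_true(all(post$Cla == 0))
  # oxygen untouched by the exchange: equals the pre-event value
  pre <- traj[traj$time_h %in% post$time_h & traj$event_flag == 0L, ]
  pre <- pre[pre$time_h > 0, ]
  expect_equal(post$Co, pre$Co)
})

test_that("refreshment events fall at period multiples, excluding the final instant", {
  count_events <- function(p, d) {
    length(perfusim:::refreshment_times(refreshment_regime(p, 1, d)))
  }
  # the generic count over 'd' days with period 'p' is floor(24 d / p)
  for (case in list(c(36, 28), c(9, 28), c(55, 28), c(120, 28), c(5, 3))) {
    p <- case[1]; d <- case[2]
    expect_identical(count_events(p, d), as.integer(floor(24 * d / p)))
  }
  # when the period divides the duration exactly, the event that would
  # fall at the final instant is dropped (it cannot affect any outcome)
  expect_identical(count_events(48, 28), 13L)
  expect_identical(count_events(24, 2), 1L)

  ref <- ref_config()
  traj <- simulate_culture(ref$params, regime = refreshment_regime(36, 0.5, 6))
  ev <- attr(traj, "events")
  expect_equal(ev$time_h, 36 * seq_len(nrow(ev)))
})

test_that("growth factor follows its exponential closed form between events", {
  ref <- ref_config()
  set.seed(21)
  for (gf0 in c(1, stats::runif(2, 0.5, 60))) {
    p_h <- sample(c(18, 30, 55), 1)
    traj <- simulate_culture(ref$params, medium = medium_spec(gf0 = gf0),
                             regime = refreshment_regime(p_h, 0.7, 5))
    # reconstruct per segment from the state at the segment start
    starts <- which(traj$event_flag == 1L | traj$time_h == 0)
    bounds <- c(traj$time_h[starts], Inf)
    for (k in seq_along(starts)) {
      # strictly inside the segment: the pre-event row at the next event
      # time still belongs here, the one at the segment start does not
      seg <- traj[traj$time_h > bounds[k] & traj$time_h <= bounds[k + 1] &
                    traj$event_flag == 0L, ]
      gf_start <- traj$gf[starts[k]]
      expected <- gf_start * 2^(-(seg$time_h - bounds[k]) / 1.5)
      expect_equal(seg$gf, expected, tolerance = 1e-6)
    }
  }
})

test_that("adaptive integration matches a 5 s fixed-step Runge-Kutta oracle", {
  # short-window cross-check at coarse oracle resolution; the full 1 s /
  # 24 h oracle comparison lives in the acceptance suite
  ref <- ref_config()
  st <- culture_state(Co = 0.192, Cg = 25, Cla = 0, V_ecm = 0,
                      V_cell = 0.0139, gf = 1)
  oracle <- rk4_culture(st, ref$params, ref$env, ref$scaffold, flow = 0.04,
                        window_h = 6, dt_s = 5, sample_h = 1)
  traj <- simulate_culture(ref$params,
                           medium = medium_spec(),
                           regime = refreshment_regime(48, 1, 0.25))
  sim <- as.data.frame(traj)[1:7, ]
  for (col in c("Co", "Cg", "Cla", "V_ecm", "V_cell", "gf")) {
    expect_equal(sim[[col]], oracle[[col]],
                 tolerance = 1e-4, ignore_attr = TRUE)
  }
})

test_that("a 28-day culture respects monotonicity and boundedness throughout", {
  ref <- ref_config()
  set.seed(31)
  regimes <- list(refreshment_regime(48, 1, 28),
                  refreshment_regime(stats::runif(1, 8, 80),
                                     stats::runif(1, 0.2, 1), 28))
  for (rg in regimes) {
    gf0 <- sample(c(1, 10, 50), 1)
    traj <- simulate_culture(ref$params, medium = medium_spec(gf0 = gf0),
                             regime = rg)
    expect_true(all(diff(traj$V_cell) >= -1e-12))
    expect_true(all(diff(traj$V_ecm) >= -1e-12))
    expect_true(all(traj$V_cell + traj$V_ecm <= 1))
    expect_true(all(traj$Co >= 0 & traj$Cg >= 0 & traj$Cla >= 0 &
                      traj$gf >= 0))
    # between events nutrients fall and lactate rises
    seg_id <- cumsum(traj$event_flag)
    for (s in split(traj, seg_id)) {
      s <- s[s$event_flag == 0L, ]
      if (nrow(s) < 2) next
      expect_true(all(diff(s$Cg) <= 1e-12))
      expect_true(all(diff(s$Co) <= 1e-12))
      expect_true(all(diff(s$Cla) >= -1e-12))
    }
  }
})

test_that("trajectories round-trip through the CSV writer with metadata", {
  ref <- ref_config()
  traj <- simulate_culture(ref$params, regime = refreshment_regime(24, 0.5, 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(traj, path)
  back <- read_trajectory(path)
  expect_identical(names(back),
                   c("time_h", "Co", "Cg", "Cla", "pH", "V_cell", "V_ecm",
                     "gf", "cells", "event_flag"))
  expect_equal(back$V_cell, traj$V_cell, tolerance = 1e-12)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"))
  expect_identical(meta$software$package, "perfusim")
  expect_equal(as.numeric(meta$n_events), 1)
  expect_equal(as.numeric(meta$config$regime$period_hours), 24)
})
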