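test_that("burn-in removes exactly the leading fraction of samples", {
  tr <- make_grid_traj(rnorm(1000, 5, 0.5))
  d <- empirical_density(tr, bins = 50, burnin_fraction = 0.1)
  expect_identical(d$n_samples, 900L)
  expect_equal(density_integral(d), 1, tolerance = 1e-12)
  expect_error(empirical_density(tr, burnin_fraction = 1), "burnin_fraction")
})

test_that("event-recorded trajectories are weighted by holding time", {
  # state 0 held for 9 time units, state 1 for 1 unit, repeated
  times <- as.numeric(rbind(seq(0, 90, by = 10), seq(9, 99, by = 10)))
  states <- rep(c(0, 1), 10)
  tr <- structure(list(times = times, states = states, seed = 0L,
                       engine = "ssa_simple", params = list(),
                       record = "events"),
                  class = "trajectory")
  d <- empirical_density(tr, bins = 2, burnin_fraction = 0,
                         range = c(-0.5, 1.5))
  mass <- d$density * d$widths
  # 10 complete low holds of 9 units, 9 complete high holds of 1 (the state
  # entered at the final event has no holding time and is dropped)
  expect_equal(mass[1], 90 / 99, tolerance = 1e-12)
  expect_equal(mass[2], 9 / 99, tolerance = 1e-12)
})

test_that("peak detection resolves a bimodal mixture and a single peak", {
  set.seed(42)
  s <- c(rnorm(5e4, 1, 0.1), rnorm(5e4, 5, 0.3))
  pk <- gaussian_peak_detect(empirical_density(make_grid_traj(s),
                                               burnin_fraction = 0))
  expect_identical(nrow(pk), 2L)
  expect_lt(abs(pk$location[1] - 1), 0.05)
  expect_lt(abs(pk$location[2] - 5), 0.05)
  s2 <- rnorm(1e5, 2, 0.5)
  pk2 <- gaussian_peak_detect(empirical_density(make_grid_traj(s2),
                                                burnin_fraction = 0))
  expect_identical(nrow(pk2), 1L)
  expect_lt(abs(pk2$location - 2), 0.02)
})

test_that("sub-threshold secondary modes are not reported", {
  set.seed(7)
  s <- c(rnorm(1e5, 2, 0.3), rnorm(30, 6, 0.1))  # 0.03% mass at 6
  d <- empirical_density(make_grid_traj(s), burnin_fraction = 0,
                         range = c(0, 7))
  pk <- gaussian_peak_detect(d, min_mass = 1e-2)
  expect_identical(nrow(pk), 1L)
  expect_lt(abs(pk$location - 2), 0.05)
})

test_that("dwell-time estimator recovers telegraph statistics", {
  tr <- telegraph_traj(mu_low = 2, mu_high = 10, t_end = 2e4, dt = 0.01,
                       seed = 7)
  dw <- dwell_times(tr, low = 0.6, high = 1.4)
  expect_gt(dw$low$n, 500)
  # dwell means within 3 standard errors of the generating rates
  expect_lt(abs(dw$low$mean - 2), 3 * 2 / sqrt(dw$low$n))
  expect_lt(abs(dw$high$mean - 10), 3 * 10 / sqrt(dw$high$n))
  expect_equal(unname(dw$occupancy["low"]), 2 / 12, tolerance = 0.15)
})

test_that("monostable signals yield one state and zero switches", {
  tr <- make_grid_traj(rnorm(5000, 3, 0.1))
  dw <- dwell_times(tr, low = 0.5, high = 1.5)
  expect_identical(dw$n_switches, 0L)
  expect_identical(dw$low$n, 0L)
  expect_equal(unname(dw$occupancy["high"]), 1)
})

test_that("crossings inside the hysteresis band are not switches", {
  # oscillates between 0.8 and 1.2, strictly inside the (0.5, 1.5) band,
  # after an initial commitment to the high state
  s <- c(rep(2, 10), rep(c(0.8, 1.2), 200))
  dw <- dwell_times(make_grid_traj(s), low = 0.5, high = 1.5)
  expect_identical(dw$n_switches, 0L)
  expect_equal(unname(dw$occupancy["high"]), 1)
})

test_that("hysteresis band stays between the density modes", {
  spec <- build_langevin(REF_MODEL, 12.5)
  ex <- density_extrema(spec, 2.4)
  thr <- hysteresis_band(ex)
  expect_true(thr[1] > ex$maxima[1] && thr[1] < ex$minima[1])
  expect_true(thr[2] > ex$minima[1] && thr[2] < ex$maxima[2])
})

test_that("diagram sweep reproduces fold endpoints and the widened window", {
  b_grid <- seq(1.6, 3.0, by = 0.05)
  diag <- diagram_sweep(REF_MODEL, b_grid, Omega = 50,
                        methods = c("deterministic", "langevin", "exact"))
  expect_length(diag$failures, 0L)
  iv_det <- diag$intervals$deterministic
  expect_lt(abs(iv_det[1] - REF_DET$lower$b_star), 0.051)
  expect_lt(abs(iv_det[2] - REF_DET$upper$b_star), 0.051)
  # stochastic methods extend the window on the upper side
  expect_gt(diag$intervals$langevin[2], iv_det[2])
  expect_gt(diag$intervals$exact[2], iv_det[2])
  # tidy records contract
  expect_named(diag$records, c("method", "b", "x", "type"))
  det_recs <- diag$records[diag$records$method == "deterministic", ]
  resid <- abs(REF_MODEL$g(det_recs$x, det_recs$b) - det_recs$x)
  expect_true(all(resid < 1e-8))
})

test_that("simulation sweep detects both branches inside the window", {
  # min_mass raised above the sparse-tail level of a finite histogram so
  # only the two genuine modes are reported
  diag <- diagram_sweep(REF_MODEL, c(2.3, 2.4), Omega = 12.5,
                        methods = "simulation", engine = "ssa",
                        seed = 42, t_end = 5000,
                        peak_cfg = list(min_mass = 0.02))
  expect_length(diag$failures, 0L)
  sim <- diag$records
  expect_true(all(table(sim$b) == 2))  # two detected peaks per b
  ex <- density_extrema(build_langevin(REF_MODEL, 12.5), 2.4)
  got <- sort(sim$x[sim$b == 2.4])
  expect_lt(max(abs(got - ex$maxima)), 0.06)
})
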