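test_that("Euler-Maruyama is reproducible and seed-sensitive", {
  spec <- build_langevin(REF_MODEL, 50)
  t1 <- euler_maruyama(spec, 2.2, x0 = 1.7, t_end = 5, seed = 7)
  t2 <- euler_maruyama(spec, 2.2, x0 = 1.7, t_end = 5, seed = 7)
  t3 <- euler_maruyama(spec, 2.2, x0 = 1.7, t_end = 5, seed = 8)
  expect_identical(t1$states, t2$states)
  expect_false(identical(t1$states, t3$states))
  expect_true(all(t1$states >= 0))
  expect_true(all(diff(t1$times) > 0))
})

test_that("zero-noise integration converges to the deterministic flow", {
  spec <- build_langevin(REF_MODEL, 50)
  x_inf <- max(deterministic_fixed_points(2.2, REF_MODEL))
  # global error O(dt): error roughly halves when dt is halved
  ref <- euler_maruyama(spec, 2.2, x0 = 0.9, t_end = 5, seed = 1,
                        dt = 1e-4 / 4, epsilon = 0)
  xT_ref <- ref$states[length(ref$states)]
  errs <- vapply(c(2e-3, 1e-3), function(dd) {
    tr <- euler_maruyama(spec, 2.2, x0 = 0.9, t_end = 5, seed = 1, dt = dd,
                         epsilon = 0)
    abs(tr$states[length(tr$states)] - xT_ref)
  }, numeric(1))
  expect_equal(errs[1] / errs[2], 2, tolerance = 0.25)
  # long-time limit is the stable fixed point
  tr <- euler_maruyama(spec, 2.2, x0 = 0.9, t_end = 30, seed = 1,
                       epsilon = 0)
  expect_equal(tr$states[length(tr$states)], x_inf, tolerance = 1e-3)
})

test_that("additive-noise sampling has the OU stationary variance", {
  eps <- 0.1
  spec <- langevin_custom(function(x, b) -x,
                          function(x, b) rep(1, length(x)), eps)
  tr <- euler_maruyama(spec, x0 = 0, t_end = 500, seed = 3, reflect = FALSE)
  s <- tr$states[-seq_len(5e4)]  # burn-in 50 time units
  v <- var(s)
  # correlation time is 1, so n_eff ~ T / 2; SE(var) ~ var * sqrt(2/n_eff)
  se <- (eps^2 / 2) * sqrt(2 / (450 / 2))
  expect_lt(abs(v - eps^2 / 2), 3 * se)
})

test_that("stability guard and mandatory seed are enforced", {
  spec <- build_langevin(REF_MODEL, 50)
  expect_error(euler_maruyama(spec, 2.2, 1, t_end = 5, seed = 1, dt = 0.1),
               "stability")
  expect_error(euler_maruyama(spec, 2.2, 1, t_end = 5, seed = NULL), "seed")
  expect_error(ssa_simple(REF_MODEL, 2.2, 50, 10, t_end = 5), "seed")
})

test_that("pure death process decays exponentially in the mean", {
  m0 <- regulatory_model(function(x, b) rep(0, length(x)), kind = "none",
                         b_range = c(0, 1))
  finals <- vapply(1:400, function(s) {
    tr <- ssa_simple(m0, 0, 1, n0 = 100, t_end = 1, seed = s)
    tr$states[length(tr$states)]
  }, numeric(1))
  expt <- 100 * exp(-1)
  se <- sqrt(100 * exp(-1) * (1 - exp(-1))) / sqrt(length(finals))
  expect_lt(abs(mean(finals) - expt), 3 * se)
})

test_that("SSA replays the exact event sequence under a fixed seed", {
  t1 <- ssa_simple(REF_MODEL, 2.2, 12.5, n0 = 20, t_end = 50, seed = 11)
  t2 <- ssa_simple(REF_MODEL, 2.2, 12.5, n0 = 20, t_end = 50, seed = 11)
  expect_identical(t1$times, t2$times)
  expect_identical(t1$states, t2$states)
  expect_identical(t1$record, "events")
  expect_true(all(t1$states == round(t1$states) & t1$states >= 0))
  expect_true(all(diff(t1$times) > 0))
})

test_that("SSA histogram agrees with the exact stationary law", {
  tr <- ssa_simple(REF_MODEL, 2.2, 12.5, n0 = 22, t_end = 2e5, seed = 3,
                   record_dt = 0.1)
  expect_gt(tr$n_events, 1e6)
  counts <- tr$states[-seq_len(2e4)]  # burn-in t = 2000
  d <- birth_death_stationary(REF_MODEL, 2.2, 12.5)
  expect_lt(tv_to_distribution(counts, d), 0.02)
})

test_that("OU generator has the exact stationary law and memory", {
  ou <- ou_config(tau = 0.5, epsilon = 0.3)
  expect_equal(ou$stationary_variance, 0.09)
  op <- ou_path(ou, t_end = 2000, seed = 31)
  z <- op$states
  expect_lt(abs(var(z) - 0.09) / 0.09, 0.1)
  lag <- round(0.5 / 1e-3)  # one correlation time
  ac <- mean(z[seq_len(length(z) - lag)] * z[-seq_len(lag)])
  theory <- 0.09 * exp(-1)
  # n_eff ~ T / (2 tau) independent stretches
  se <- 0.09 * sqrt(2 / (2000 / 1))
  expect_lt(abs(ac - theory), 3 * se)
})

test_that("colored integrator approaches the deterministic flow at long tau", {
  spec <- build_langevin(REF_MODEL, 12.5)
  x_hi <- max(deterministic_fixed_points(2.4, REF_MODEL))
  tr <- colored_langevin(spec, 2.4, ou_config(tau = 1e4, epsilon = spec$epsilon),
                         x0 = x_hi, t_end = 100, seed = 5)
  # OU variance eps^2/(2 tau) is tiny: trajectory hugs the fixed point
  expect_lt(max(abs(tr$states[-seq_len(100)] - x_hi)), 0.05)
})

test_that("detailed model conserves promoter copies and stays non-negative", {
  p <- detailed_switch_params(a = 0.1, b = 2.4, h = 2, Omega = 12.5,
                              dna_copies = 2L)
  tr <- ssa_detailed(p, t_end = 200, seed = 9, n0 = 20)
  expect_true(all(tr$d1 >= 0 & tr$d1 <= 2))
  expect_true(all(tr$states >= 0))
  expect_true(all(tr$states == round(tr$states)))
  t2 <- ssa_detailed(p, t_end = 200, seed = 9, n0 = 20)
  expect_identical(tr$states, t2$states)
})

test_that("clamped-protein occupancy matches the two-state equilibrium", {
  p <- detailed_switch_params(a = 0.1, b = 3, h = 2, Omega = 50)
  oc <- promoter_occupancy_ssa(p, n_clamped = 100, t_end = 3000, seed = 9)
  # p = 2, occupancy 4/5; switching rate ~ koff so dwells are ~1e-2:
  # SE ~ sqrt(p(1-p) * 2*tau_c / T) with tau_c ~ 1/(koff(1+keq p^h))
  se <- sqrt(0.8 * 0.2 * 2 * (1 / 500) / 3000)
  expect_lt(abs(oc$occupancy - oc$qss_occupancy), 3 * se + 0.003)
  expect_equal(oc$qss_occupancy, 0.8)
})
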