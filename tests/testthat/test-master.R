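test_that("constant production gives the Poisson law exactly", {
  lam <- 7.3
  mc <- regulatory_model(function(x, b) rep(lam / 10, length(x)),
                         kind = "const", b_range = c(0, 1))
  d <- birth_death_stationary(mc, b = 0, Omega = 10)  # mean = 7.3
  expect_lt(max(abs(d$probs - dpois(d$n, lam))), 1e-12)
  expect_identical(discrete_modes(d), 7L)
  expect_lt(detailed_balance_residual(d, mc), 1e-12)
})

test_that("distribution is normalized with a controlled tail", {
  d <- birth_death_stationary(REF_MODEL, b = 2.2, Omega = 12.5)
  expect_true(sum(d$probs) >= 1 - 1e-9 && sum(d$probs) <= 1 + 1e-9)
  expect_lt(d$probs[length(d$probs)], 1e-10 * max(d$probs))
  expect_true(all(d$probs >= 0))
  expect_lt(detailed_balance_residual(d, REF_MODEL), 1e-12)
})

test_that("modes handle boundary and plateau cases", {
  # strictly decreasing distribution: boundary mode at n = 0
  dec <- birth_death_stationary(
    regulatory_model(function(x, b) rep(0.05, length(x)), kind = "const",
                     b_range = c(0, 1)), b = 0, Omega = 10)  # Poisson(0.5)
  expect_identical(discrete_modes(dec), 0L)
  # plateau resolved to the smallest n
  fake <- list(n = 0:5, probs = c(0.1, 0.2, 0.2, 0.2, 0.2, 0.1))
  expect_identical(discrete_modes(fake), 1L)
})

test_that("switch is bimodal at small volume inside the widened window", {
  # b above the deterministic upper fold: deterministically monostable,
  # stochastically still bimodal (noise-induced bistability)
  expect_gt(2.7, REF_DET$upper$b_star)
  d <- birth_death_stationary(REF_MODEL, b = 2.7, Omega = 12.5)
  expect_length(discrete_modes(d), 2L)
})

test_that("truncation auto-extends and the cap errors out", {
  d <- birth_death_stationary(REF_MODEL, b = 2.2, Omega = 12.5, n_max = 5)
  expect_gt(length(d$n), 6L)  # doubled past the requested truncation
  expect_error(
    birth_death_stationary(REF_MODEL, b = 2.2, Omega = 12.5, n_max = 5,
                           n_cap = 10),
    "cap")
})

test_that("exact modes track the analytic density maxima as volume grows", {
  errs <- vapply(c(12.5, 200), function(Om) {
    spec <- build_langevin(REF_MODEL, Om)
    md <- discrete_modes(birth_death_stationary(REF_MODEL, 2.2, Om)) / Om
    mx <- density_extrema(spec, 2.2)$maxima
    max(abs(sort(md) - sort(mx)))
  }, numeric(1))
  expect_lt(errs[1], 1 / 12.5)
  expect_lt(errs[2], 1 / 200)
  expect_lt(errs[2], errs[1])
})
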