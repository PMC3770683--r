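test_that("order zero reproduces the deterministic saddle-node", {
  for (br in c("lower", "upper")) {
    s0 <- shift_series(REF_MODEL, br, order = 0)
    expect_equal(s0$b_coeffs, REF_DET[[br]]$b_star)
    expect_equal(s0$x_coeffs, REF_DET[[br]]$x_star)
    # zero noise: no shift at any order
    p <- predict_shift(shift_series(REF_MODEL, br, order = 2), epsilon = 0)
    expect_equal(p$b_star, REF_DET[[br]]$b_star)
    expect_equal(p$x_star, REF_DET[[br]]$x_star)
  }
})

test_that("first-order coefficients match their closed form at the fold", {
  # at the fold g_x = 1, so B_x = 2 and b1 = 1 / g_b = (1 + x0^h) / x0^h
  for (br in c("lower", "upper")) {
    s1 <- shift_first_order(REF_MODEL, br)
    x0 <- REF_DET[[br]]$x_star
    expect_equal(s1$b1, (1 + x0^2) / x0^2, tolerance = 1e-9)
  }
  # upper fold of the low state: positive b-shift, negative x-shift
  s1u <- shift_first_order(REF_MODEL, "upper")
  expect_gt(s1u$b1, 0)
  expect_lt(s1u$x1, 0)
})

test_that("activator delays and inhibitor advances the bifurcation", {
  expect_gt(shift_first_order(REF_MODEL, "lower")$b1, 0)
  expect_gt(shift_first_order(REF_MODEL, "upper")$b1, 0)
  mi <- hill_inhibitor(a = 0.1, h = 2, c = 4)
  expect_lt(shift_first_order(mi, "lower")$b1, 0)
  expect_lt(shift_first_order(mi, "upper")$b1, 0)
})

test_that("first order matches the small-noise limit of the continuation", {
  spec <- build_langevin(REF_MODEL, 50)
  for (br in c("lower", "upper")) {
    s1 <- shift_first_order(REF_MODEL, br)
    slope <- vapply(c(1e-4, 5e-5), function(s)
      (stochastic_bifurcation_solve(spec, br, epsilon = sqrt(s))$b_star -
         s1$b0) / s, numeric(1))
    # Richardson extrapolation removes the O(s) second-order contamination
    expect_equal(2 * slope[2] - slope[1], s1$b1, tolerance = 1e-3)
  }
})

test_that("order-1 truncation error scales as the square of the intensity", {
  spec <- build_langevin(REF_MODEL, 50)
  for (br in c("lower", "upper")) {
    s1 <- shift_first_order(REF_MODEL, br)
    err <- vapply(c(1e-3, 5e-4), function(s) {
      bp <- stochastic_bifurcation_solve(spec, br, epsilon = sqrt(s))
      abs(bp$b_star - s1$b0 - s * s1$b1)
    }, numeric(1))
    expect_gt(err[1] / err[2], 3)
    expect_lt(err[1] / err[2], 5)
  }
})

test_that("second order beats first order against the continuation", {
  spec <- build_langevin(REF_MODEL, 50)
  ser1 <- shift_series(REF_MODEL, "upper", order = 1)
  ser2 <- shift_series(REF_MODEL, "upper", order = 2)
  for (s in c(1e-2, 3e-3, 1e-3)) {
    b_exact <- stochastic_bifurcation_solve(spec, "upper",
                                            epsilon = sqrt(s))$b_star
    e1 <- abs(b_exact - predict_shift(ser1, sqrt(s))$b_star)
    e2 <- abs(b_exact - predict_shift(ser2, sqrt(s))$b_star)
    expect_lt(e2, e1)
  }
})

test_that("long-correlation-time shift is exactly half the white-noise one", {
  for (br in c("lower", "upper")) {
    cs <- colored_longtau_shift(REF_MODEL, br)
    expect_identical(cs$b1, cs$b1_white / 2)
    expect_identical(cs$x1, cs$x1_white / 2)
    expect_identical(sign(cs$b1), sign(cs$b1_white))
    # magnitude is lessened but the sign survives
    expect_lt(abs(cs$b1), abs(cs$b1_white))
  }
  # series form: coefficient of s^k scaled by 2^-k, constant term untouched
  sw <- shift_series(REF_MODEL, "upper", 2, noise_kind = "white")
  sc <- shift_series(REF_MODEL, "upper", 2, noise_kind = "colored_long_tau")
  expect_equal(sc$b_coeffs, sw$b_coeffs / c(1, 2, 4))
})

test_that("expansion fails loudly without a bistable region", {
  expect_error(shift_first_order(hill_activator(a = 0.1, h = 1), "lower"),
               "bistable")
})
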