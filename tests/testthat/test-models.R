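test_that("Hill production rate has the right limits and monotonicity", {
  p <- list(a = 0.1, b = 1, h = 2)
  expect_identical(hill_g(0, p), 0.1)                    # leakiness at x = 0
  expect_equal(hill_g(1e6, p), 1.1, tolerance = 1e-10)   # saturation a + b
  expect_equal(hill_g(1, list(a = 0.1, b = 0.8, h = 2)), 0.5)  # half-max
  xs <- seq(0, 20, length.out = 500)
  for (h in c(1, 2, 4))
    expect_true(all(diff(hill_g(xs, list(a = 0.1, b = 2, h = h))) >= 0))
  expect_error(hill_g(-0.5, p), "negative")
})

test_that("parameter records enforce their invariants", {
  expect_error(hill_switch_params(a = 0), "'a'")
  expect_error(hill_switch_params(b = -1), "'b'")
  expect_error(hill_switch_params(h = 1.5), "'h'")
  expect_error(hill_switch_params(Omega = 0), "'Omega'")
  expect_error(detailed_switch_params(keq = -1), "'keq'")
  expect_error(detailed_switch_params(dna_copies = 0), "dna_copies")
  expect_warning(detailed_switch_params(koff = 5), "koff")
  expect_silent(detailed_switch_params(koff = 100))
})

test_that("Langevin spec wires drift, diffusion and noise intensity", {
  spec <- build_langevin(REF_MODEL, Omega = 100)
  expect_equal(spec$epsilon, 0.1)
  expect_equal(spec$diffusion_shape(0, 2), 0.1)  # B(0) = g(0) = a
  expect_error(build_langevin(REF_MODEL, Omega = -1), "Omega")
  # drift zero exactly at fixed points, B > 0 on the working domain
  fps <- deterministic_fixed_points(2.2, REF_MODEL)
  expect_true(all(abs(spec$drift(fps, 2.2)) < 1e-10))
  xs <- seq(0, 6, length.out = 200)
  expect_true(all(spec$diffusion_shape(xs, 2.2) > 0))
  # infinite volume limit
  expect_lt(build_langevin(REF_MODEL, 1e12)$epsilon, 1e-5)
})

test_that("closed-form Hill derivatives match finite differences", {
  for (h in c(1L, 2L, 3L, 4L)) {
    m <- hill_activator(a = 0.13, h = h)
    fd <- regulatory_model(m$g, dg = NULL, b_range = m$b_range)
    for (x in c(0.31, 0.9, 2.7)) {
      for (k in 1:4) {
        an <- m$dg(x, 1.7, k, 0L)
        nu <- fd$dg(x, 1.7, k, 0L)
        expect_lt(abs(nu - an), 2e-3 * max(1, abs(an)))
      }
      expect_lt(abs(fd$dg(x, 1.7, 1L, 1L) - m$dg(x, 1.7, 1L, 1L)), 1e-5)
    }
  }
  # exact limits at the boundary
  m2 <- hill_activator(a = 0.1, h = 2)
  expect_equal(m2$dg(0, 1, 1L, 0L), 0)   # H'(0) = 0 for h = 2
  expect_equal(m2$dg(0, 1, 2L, 0L), 2)   # H''(0) = 2 for h = 2
})

test_that("fixed points match an independent sign-scan oracle", {
  for (b in c(0, 1.2, 2.2, 3.2)) {
    got <- deterministic_fixed_points(b, REF_MODEL)
    # oracle: brute-force uniroot scan of g - x, independent of polyroot
    f <- function(x) REF_MODEL$g(x, b) - x
    xs <- seq(0, 10, length.out = 4000)
    fs <- f(xs)
    idx <- which(fs[-length(fs)] * fs[-1] < 0)
    oracle <- sort(vapply(idx, function(i)
      uniroot(f, c(xs[i], xs[i + 1]), tol = 1e-13)$root, numeric(1)))
    expect_equal(got, oracle, tolerance = 1e-8)
    expect_true(all(abs(f(got)) < 1e-10))
    expect_true(length(got) %in% c(1L, 3L))
  }
  expect_length(deterministic_fixed_points(0, REF_MODEL), 1L)
  expect_length(deterministic_fixed_points(2.2, REF_MODEL), 3L)
})

test_that("saddle-nodes match the hand-reduced cubic oracle", {
  or <- hill2_saddle_oracle(0.1)
  expect_true(REF_DET$bistable)
  expect_equal(REF_DET$lower$b_star, or$b[1], tolerance = 1e-10)
  expect_equal(REF_DET$upper$b_star, or$b[2], tolerance = 1e-10)
  expect_equal(REF_DET$lower$x_star, or$x[1], tolerance = 1e-10)
  expect_equal(REF_DET$upper$x_star, or$x[2], tolerance = 1e-10)
  expect_lt(REF_DET$lower$b_star, REF_DET$upper$b_star)
  # residuals of f and f_x at the folds
  for (pt in list(REF_DET$lower, REF_DET$upper)) {
    f <- REF_MODEL$g(pt$x_star, pt$b_star) - pt$x_star
    fx <- REF_MODEL$dg(pt$x_star, pt$b_star, 1L, 0L) - 1
    expect_lt(abs(f), 1e-10)
    expect_lt(abs(fx), 1e-10)
  }
})

test_that("non-bistable models give a no-bistable-region result, not an error", {
  res <- deterministic_bifurcation_points(hill_activator(a = 0.1, h = 1))
  expect_false(res$bistable)
  res2 <- deterministic_bifurcation_points(hill_activator(a = 2, h = 2))
  expect_false(res2$bistable)
})

test_that("bistable window equals the three-root region on a b-grid", {
  bs <- seq(1.6, 2.8, by = 0.002)
  n_roots <- vapply(bs, function(b)
    length(deterministic_fixed_points(b, REF_MODEL)), integer(1))
  inside <- bs > REF_DET$lower$b_star + 0.002 &
    bs < REF_DET$upper$b_star - 0.002
  outside <- bs < REF_DET$lower$b_star - 0.002 |
    bs > REF_DET$upper$b_star + 0.002
  expect_true(all(n_roots[inside] == 3L))
  expect_true(all(n_roots[outside] == 1L))
})

test_that("inhibitor-controlled switch mirrors the activator window", {
  mi <- hill_inhibitor(a = 0.1, h = 2, c = 4)
  det <- deterministic_bifurcation_points(mi)
  expect_true(det$bistable)
  # effective activation c - b at the folds equals the activator's b values
  expect_equal(4 - det$upper$b_star, REF_DET$lower$b_star, tolerance = 1e-8)
  expect_equal(4 - det$lower$b_star, REF_DET$upper$b_star, tolerance = 1e-8)
})
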