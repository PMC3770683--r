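test_that("additive-noise density reproduces the Ornstein-Uhlenbeck law", {
  eps <- 0.1
  spec <- langevin_custom(function(x, b) -x,
                          function(x, b) rep(1, length(x)), eps)
  sg <- eps / sqrt(2)
  d <- stationary_density(spec, x_min = -6 * sg, x_max = 6 * sg)
  expect_lt(max(abs(d$density - dnorm(d$grid, 0, sg))) /
              max(dnorm(d$grid, 0, sg)), 1e-6)
  ex <- density_extrema(spec, x_min = -6 * sg, x_max = 6 * sg)
  expect_equal(ex$maxima, 0, tolerance = 1e-6)
  expect_length(ex$minima, 0L)
})

test_that("switch densities are normalized and positive", {
  for (Om in c(12.5, 50)) {
    spec <- build_langevin(REF_MODEL, Om)
    for (b in c(1.5, 2.2, 3.0)) {
      d <- stationary_density(spec, b)
      expect_equal(density_integral(d), 1, tolerance = 1e-6)
      expect_true(all(d$density >= 0))
      expect_true(all(diff(d$grid) > 0))
    }
  }
})

test_that("density is undefined where the diffusion shape vanishes", {
  spec <- langevin_custom(function(x, b) -x, function(x, b) x - 0.5, 0.1)
  expect_error(stationary_density(spec, x_min = 0, x_max = 2), "B\\(x\\)")
})

test_that("extrema converge to the deterministic fixed points as noise vanishes", {
  spec <- build_langevin(REF_MODEL, 50)
  fps <- deterministic_fixed_points(2.2, REF_MODEL)
  ex <- density_extrema(spec, 2.2, epsilon = 1e-6)
  expect_equal(sort(c(ex$maxima, ex$minima)), fps, tolerance = 1e-4)
  # maxima and minima interleave
  ex2 <- density_extrema(spec, 2.2)
  expect_length(ex2$maxima, 2L)
  expect_length(ex2$minima, 1L)
  expect_true(ex2$maxima[1] < ex2$minima[1] &&
                ex2$minima[1] < ex2$maxima[2])
})

test_that("low-state density maximum shifts below its deterministic value", {
  spec <- build_langevin(REF_MODEL, 50)
  fps <- deterministic_fixed_points(2.2, REF_MODEL)
  ex <- density_extrema(spec, 2.2, epsilon = 0.05)
  expect_lt(ex$maxima[1], fps[1])
})

test_that("density maxima agree with the extremum condition", {
  spec <- build_langevin(REF_MODEL, 12.5)
  d <- stationary_density(spec, 2.3)
  ex <- density_extrema(spec, 2.3)
  dx <- d$grid[2] - d$grid[1]
  # local argmax refinement of the gridded density
  p <- d$density
  k <- length(p)
  loc <- d$grid[which(c(FALSE, p[2:(k - 1)] > p[1:(k - 2)] &
                          p[2:(k - 1)] >= p[3:k], FALSE))]
  for (mx in ex$maxima[ex$maxima > dx])
    expect_lt(min(abs(loc - mx)), 2 * dx)
})

test_that("continuation at zero noise reproduces the deterministic folds", {
  spec <- build_langevin(REF_MODEL, 50)
  for (br in c("lower", "upper")) {
    bp <- stochastic_bifurcation_solve(spec, br, epsilon = 0)
    expect_equal(bp$b_star, REF_DET[[br]]$b_star, tolerance = 1e-10)
    expect_equal(bp$x_star, REF_DET[[br]]$x_star, tolerance = 1e-10)
    expect_true(bp$converged)
  }
})

test_that("continuation shifts both folds right, monotonically in noise", {
  spec <- build_langevin(REF_MODEL, 50)
  eps_grid <- c(0.05, 0.1, 0.15, 0.2)
  for (br in c("lower", "upper")) {
    bstars <- vapply(eps_grid, function(e)
      stochastic_bifurcation_solve(spec, br, epsilon = e)$b_star, numeric(1))
    expect_true(all(bstars > REF_DET[[br]]$b_star))
    expect_true(all(diff(bstars) > 0))
  }
})

test_that("continuation residuals meet the stated tolerance", {
  spec <- build_langevin(REF_MODEL, 50)
  bp <- stochastic_bifurcation_solve(spec, "upper")
  expect_lt(bp$residual, 1e-10)
  expect_identical(bp$method, "continuation")
})

test_that("density modality changes exactly at the continuation folds", {
  spec <- build_langevin(REF_MODEL, 50)
  lo <- stochastic_bifurcation_solve(spec, "lower")$b_star
  hi <- stochastic_bifurcation_solve(spec, "upper")$b_star
  for (b in seq(lo + 0.03, hi - 0.03, length.out = 6))
    expect_length(density_extrema(spec, b)$maxima, 2L)
  for (b in c(lo - 0.05, hi + 0.05))
    expect_length(density_extrema(spec, b)$maxima, 1L)
})
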