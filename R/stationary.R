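## Analytic stationary density of the Ito Langevin equation, its extrema,
## and numerical continuation of the stochastic bifurcation conditions.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

cumtrapz1 <- function(x, y) {
  n <- length(x)
  c(0, cumsum((y[-1] + y[-n]) / 2 * diff(x)))
}

#' Stationary probability density of the Ito Langevin equation
#'
#' For `dx = f(x, b) dt + epsilon * sqrt(B(x, b)) dW` (Ito), the stationary
#' density is `Ps(x) = N / B(x) * exp((2 / epsilon^2) * int^x f(y)/B(y) dy)`.
#' The exponent is accumulated by cumulative trapezoidal quadrature and the
#' normalization is done in log space, so strongly peaked densities do not
#' underflow.
#'
#' @param spec a [build_langevin()] specification.
#' @param b control parameter value.
#' @param n_grid number of (uniform) grid points.
#' @param x_max upper end of the state grid; by default 3x the largest
#'   deterministic fixed point, extended until the unnormalized tail falls
#'   below `1e-12` of the peak.
#' @param epsilon noise intensity; defaults to the spec's
#'   (`Omega^(-1/2)`). Overriding it allows density sweeps in the noise
#'   intensity without rebuilding the spec.
#' @param x_min lower end of the state grid (0 for the chemical models whose
#'   state is a concentration; custom specs may use a wider domain).
#' @return an object of class `stationary_density`: a list with `grid`,
#'   `density` (normalized), `log_density` (normalized, kept to avoid
#'   underflow), `b`, `epsilon` and the quadrature convention.
#' @examples
#' spec <- build_langevin(hill_activator(), Omega = 50)
#' d <- stationary_density(spec, b = 2.2)
#' density_integral(d)  # 1 up to quadrature error
#' @export
stationary_density <- function(spec, b = NA_real_, n_grid = 4001L,
                               x_max = NULL, epsilon = NULL, x_min = 0) {
  stopifnot(inherits(spec, "langevin_spec"))
  eps <- if (is.null(epsilon)) spec$epsilon else epsilon
  if (eps <= 0) stop("'epsilon' must be > 0")
  if (is.null(x_max)) {
    if (is.null(spec$model))
      stop("'x_max' must be given for a custom langevin_spec")
    fps <- deterministic_fixed_points(b, spec$model)
    x_max <- 3 * max(fps, 0.2)
  }
  for (i in 1:30) {
    xs <- seq(x_min, x_max, length.out = n_grid)
    Bv <- spec$diffusion_shape(xs, b)
    if (any(Bv <= 0))
      stop("diffusion shape B(x) <= 0 on the grid; stationary density undefined")
    fv <- spec$drift(xs, b)
    logp <- -log(Bv) + (2 / eps^2) * cumtrapz1(xs, fv / Bv)
    if (logp[n_grid] - max(logp) < log(1e-12)) break
    x_max <- x_max * 1.5
  }
  dx <- xs[2] - xs[1]
  w <- rep(dx, n_grid); w[c(1, n_grid)] <- dx / 2  # trapezoid weights
  logZ <- logsumexp(logp + log(w))
  structure(list(grid = xs, density = exp(logp - logZ),
                 log_density = logp - logZ, b = b, epsilon = eps,
                 quadrature = "trapezoid"),
            class = "stationary_density")
}

#' Integral of a stationary density over its grid
#'
#' Uses the quadrature convention the object was built with (trapezoid for
#' analytic densities, bin sums for histogram densities), so a valid density
#' integrates to 1 up to the stated tolerance.
#'
#' @param d a `stationary_density`.
#' @return the integral (scalar).
#' @export
density_integral <- function(d) {
  stopifnot(inherits(d, "stationary_density"))
  if (identical(d$quadrature, "midpoint")) {
    sum(d$density * d$widths)
  } else {
    sum((d$density[-1] + d$density[-length(d$density)]) / 2 * diff(d$grid))
  }
}

#' @export
print.stationary_density <- function(x, ...) {
  cat("<stationary_density> on [0,", format(max(x$grid), digits = 4),
      "] (", length(x$grid), "points )\n")
  cat("  b =", x$b, " epsilon =", format(x$epsilon, digits = 6),
      " integral =", format(density_integral(x), digits = 8), "\n")
  invisible(x)
}

# Extremum function Phi(x, b, s) = f - (s/2) B_x and its derivatives,
# s = epsilon^2. Roots of Phi in x are the density extrema (Ito convention).
phi_deriv <- function(model, x, b, s, ix = 0L, ib = 0L) {
  spec_f_deriv(model, x, b, ix, ib) -
    (s / 2) * spec_B_deriv(model, x, b, ix + 1L, ib)
}

# Phi for custom specs (no regulatory model): finite differences of the
# spec-level drift/diffusion functions.
phi_spec <- function(spec, x, b, s, ix = 0L) {
  hh <- 6e-6 * pmax(1, abs(x))
  Bx <- (spec$diffusion_shape(x + hh, b) -
           spec$diffusion_shape(x - hh, b)) / (2 * hh)
  ph <- spec$drift(x, b) - (s / 2) * Bx
  if (ix == 0L) return(ph)
  h2 <- 1e-5 * pmax(1, abs(x))
  (phi_spec(spec, x + h2, b, s) - phi_spec(spec, x - h2, b, s)) / (2 * h2)
}

#' Extrema of the stationary density
#'
#' The extrema of the stationary density of the Ito Langevin equation solve
#' `Phi(x) = f(x, b) - (epsilon^2 / 2) * dB/dx(x, b) = 0`; a root is a
#' maximum where `dPhi/dx < 0` and a minimum where `dPhi/dx > 0`. As
#' `epsilon -> 0` the extrema converge to the deterministic fixed points.
#'
#' @inheritParams stationary_density
#' @param x_max upper end of the search interval (default as in
#'   [stationary_density()]).
#' @return an object of class `extrema_set`: list with sorted numeric vectors
#'   `maxima` and `minima`, plus `b` and `epsilon`.
#' @export
density_extrema <- function(spec, b = NA_real_, x_max = NULL, epsilon = NULL,
                            x_min = NULL) {
  stopifnot(inherits(spec, "langevin_spec"))
  eps <- if (is.null(epsilon)) spec$epsilon else epsilon
  s <- eps^2
  model <- spec$model
  phi <- if (is.null(model)) {
    function(x, ix = 0L) phi_spec(spec, x, b, s, ix)
  } else {
    function(x, ix = 0L) phi_deriv(model, x, b, s, ix)
  }
  if (is.null(x_max)) {
    if (is.null(model))
      stop("'x_max' must be given for a custom langevin_spec")
    fps <- deterministic_fixed_points(b, model)
    x_max <- 3 * max(fps, 0.2) + 10 * s
  }
  if (is.null(x_min)) x_min <- 1e-9
  xs <- seq(x_min, x_max, length.out = 4001L)
  ph <- phi(xs)
  idx <- which(ph[-length(ph)] * ph[-1] <= 0 & ph[-length(ph)] != 0)
  roots <- vapply(idx, function(i) {
    uniroot(function(x) phi(x), c(xs[i], xs[i + 1]), tol = 1e-13)$root
  }, numeric(1))
  # Newton polish
  tol_root <- if (is.null(model)) 1e-9 else 1e-13
  roots <- vapply(roots, function(r) {
    for (k in 1:40) {
      p  <- phi(r)
      if (abs(p) < tol_root) break
      dp <- phi(r, ix = 1L)
      if (!is.finite(dp) || abs(dp) < 1e-14) break
      r <- r - p / dp
    }
    r
  }, numeric(1))
  roots <- sort(roots[roots > x_min & roots <= x_max])
  if (length(roots) > 1) roots <- roots[c(TRUE, diff(roots) > 1e-9)]
  slope <- phi(roots, ix = 1L)
  structure(list(maxima = roots[slope < 0], minima = roots[slope > 0],
                 b = b, epsilon = eps),
            class = "extrema_set")
}

#' @export
print.extrema_set <- function(x, ...) {
  cat("<extrema_set> b =", x$b, " epsilon =", format(x$epsilon, digits = 6),
      "\n  maxima:", paste(format(x$maxima, digits = 8), collapse = ", "),
      "\n  minima:", paste(format(x$minima, digits = 8), collapse = ", "), "\n")
  invisible(x)
}

#' Stochastic bifurcation point by numerical continuation
#'
#' A stochastic (phenomenological) bifurcation occurs where the stationary
#' density changes modality, i.e. where an extremum appears or disappears:
#' `Phi(x, b) = 0` and `dPhi/dx(x, b) = 0` simultaneously, with
#' `Phi = f - (epsilon^2 / 2) dB/dx`. The solution is seeded at the
#' deterministic saddle-node (`epsilon = 0`, where the conditions reduce to
#' `f = 0`, `df/dx = 0`) and path-followed in `s = epsilon^2` with adaptive
#' steps; each step is converged by a 2-D Newton iteration to residuals below
#' `1e-12`.
#'
#' @param spec a [build_langevin()] specification.
#' @param branch `"lower"` or `"upper"` deterministic saddle-node to
#'   continue.
#' @param epsilon target noise intensity (defaults to the spec's).
#' @param ds0 initial step in `s = epsilon^2`.
#' @return a [bifurcation_point()] with `method = "continuation"` and fields
#'   `epsilon`, `residual`, `converged`. If the branch is lost before the
#'   target (Newton failure at the minimum step), the point reached last is
#'   returned with `converged = FALSE` and `epsilon_reached`.
#' @export
stochastic_bifurcation_solve <- function(spec, branch = c("lower", "upper"),
                                         epsilon = NULL, ds0 = 1e-4) {
  stopifnot(inherits(spec, "langevin_spec"))
  branch <- match.arg(branch)
  eps <- if (is.null(epsilon)) spec$epsilon else epsilon
  s_target <- eps^2
  model <- spec$model
  det <- deterministic_bifurcation_points(model)
  if (!det$bistable)
    stop("no deterministic bistable region: cannot seed the continuation")
  pt <- det[[branch]]
  x <- pt$x_star; b <- pt$b_star
  s <- 0
  ds <- min(ds0, max(s_target / 10, 1e-8))
  while (s < s_target) {
    s_next <- min(s + ds, s_target)
    sol <- phi_fold_newton(model, x, b, s_next)
    if (is.null(sol)) {
      ds <- ds / 2
      if (ds < 1e-10) {
        return(bifurcation_point(b, x, branch = branch,
                                 method = "continuation",
                                 epsilon = eps, epsilon_reached = sqrt(s),
                                 converged = FALSE,
                                 residual = NA_real_))
      }
    } else {
      x <- sol$x; b <- sol$b; s <- s_next
      ds <- ds * 1.6
    }
  }
  res <- max(abs(phi_deriv(model, x, b, s)),
             abs(phi_deriv(model, x, b, s, ix = 1L)))
  bifurcation_point(b, x, branch = branch, method = "continuation",
                    epsilon = eps, converged = TRUE, residual = res)
}

# 2-D Newton on (Phi, Phi_x) = 0 at fixed s; returns NULL on failure.
phi_fold_newton <- function(model, x0, b0, s, tol = 1e-12, maxit = 50L) {
  x <- x0; b <- b0
  for (i in seq_len(maxit)) {
    p  <- phi_deriv(model, x, b, s)
    px <- phi_deriv(model, x, b, s, ix = 1L)
    if (max(abs(p), abs(px)) < tol) return(list(x = x, b = b))
    pb  <- phi_deriv(model, x, b, s, ib = 1L)
    pxx <- phi_deriv(model, x, b, s, ix = 2L)
    pxb <- phi_deriv(model, x, b, s, ix = 1L, ib = 1L)
    det <- px * pxb - pb * pxx
    if (!is.finite(det) || abs(det) < 1e-16) return(NULL)
    dx <- ( pxb * p - pb * px) / det
    db <- (-pxx * p + px * px) / det
    if (!is.finite(dx) || !is.finite(db)) return(NULL)
    # reject wild steps: continuation supplies good seeds
    if (abs(dx) > 0.5 * max(1, abs(x)) || abs(db) > 0.5 * max(1, abs(b)))
      return(NULL)
    x <- x - dx
    b <- b - db
    if (x <= 0) return(NULL)
  }
  p  <- phi_deriv(model, x, b, s)
  px <- phi_deriv(model, x, b, s, ix = 1L)
  if (max(abs(p), abs(px)) < tol) return(list(x = x, b = b)) else NULL
}

#' Export a stationary density as CSV
#'
#' Writes columns `x`, `density`, `log_density`.
#'
#' @param d a `stationary_density`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_density_csv <- function(d, path) {
  stopifnot(inherits(d, "stationary_density"))
  write.csv(data.frame(x = d$grid, density = d$density,
                       log_density = d$log_density),
            path, row.names = FALSE)
  invisible(path)
}

#' Export bifurcation points as JSON
#'
#' Writes a JSON array of records `{branch, method, epsilon, b_star, x_star}`.
#'
#' @param points a list of [bifurcation_point()] objects.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_bifurcation_json <- function(points, path) {
  recs <- lapply(points, function(p) {
    list(branch = p$branch, method = p$method,
         epsilon = if (is.null(p$epsilon)) 0 else p$epsilon,
         b_star = p$b_star, x_star = p$x_star)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
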