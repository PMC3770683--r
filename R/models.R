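#' stochbif: stochastic bifurcation analysis of one-variable gene circuits
#'
#' Tools to quantify how intrinsic biochemical noise shifts the saddle-node
#' bifurcation points of one-dimensional gene regulatory systems, using the
#' auto-activating genetic switch as the reference model. The package covers
#' the analytic stationary density of the Ito chemical Langevin equation,
#' numerical continuation of the stochastic bifurcation conditions, a
#' perturbative expansion of the bifurcation points in the noise intensity,
#' the exact birth-death master-equation solution, stochastic simulation
#' engines (Euler-Maruyama, colored-noise Heun, Gillespie), and a landscape
#' pipeline turning trajectories into stochastic bifurcation diagrams.
#'
#' All models are nondimensionalized: concentrations are measured in units of
#' the half-maximum activation concentration and time in units of the inverse
#' degradation rate, so the degradation rate is 1 throughout.
#'
#' @useDynLib stochbif, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats D uniroot rnorm runif rexp lm coef setNames
#' @importFrom utils write.csv modifyList
#' @keywords internal
"_PACKAGE"

## ---------------------------------------------------------------------------
## Parameter records
## ---------------------------------------------------------------------------

#' Parameters of the auto-activating Hill switch
#'
#' Dimensionless parameterization of the auto-activating genetic switch: a
#' protein oligomerizes and activates its own promoter, giving the production
#' rate `g(x) = a + b * x^h / (1 + x^h)` with linear degradation at rate 1.
#' Concentration is in units of the half-maximum activation concentration and
#' time in units of the inverse degradation rate.
#'
#' @param a basal expression rate (promoter leakiness), `a > 0`.
#' @param b maximum production rate (auto-activation efficiency), the control
#'   parameter, `b >= 0`.
#' @param h cooperativity (oligomerization index), positive integer.
#' @param Omega dimensionless cellular volume, `Omega > 0`. Sets the intrinsic
#'   noise intensity `epsilon = Omega^(-1/2)`.
#' @return an object of class `hill_switch_params`.
#' @seealso [hill_g()], [hill_activator()], [build_langevin()]
#' @export
hill_switch_params <- function(a = 0.1, b = 2, h = 2, Omega = 50) {
  stopifnot(is.numeric(a), length(a) == 1L, is.finite(a),
            is.numeric(b), length(b) == 1L, is.finite(b),
            is.numeric(h), length(h) == 1L, is.finite(h),
            is.numeric(Omega), length(Omega) == 1L, is.finite(Omega))
  if (a <= 0) stop("'a' must be > 0 (promoter leakiness keeps B(x) > 0)")
  if (b < 0) stop("'b' must be >= 0")
  if (h < 1 || h != round(h)) stop("'h' must be a positive integer")
  if (Omega <= 0) stop("'Omega' must be > 0")
  structure(list(a = a, b = b, h = as.integer(h), Omega = Omega),
            class = "hill_switch_params")
}

#' Parameters of the detailed promoter-binding switch
#'
#' The detailed switch resolves the promoter explicitly: `h` protein monomers
#' bind the unbound promoter `D0` in a single cooperative event to form `D1`,
#' production runs at count rate `a * Omega` from `D0` and `(a + b) * Omega`
#' from `D1`, free protein degrades at rate `n`. Under fast binding/unbinding
#' (quasi-steady-state) the model reduces to the simple Hill switch with the
#' same `(a, b, h)` when `keq = 1`.
#'
#' @inheritParams hill_switch_params
#' @param keq binding equilibrium constant in dimensionless concentration
#'   units; `keq = 1` matches the nondimensionalization of the simple switch.
#' @param koff unbinding rate; promoter kinetics are fast relative to protein
#'   production/degradation when `koff >> 1`. Values below 10 trigger a
#'   warning (the quasi-steady-state regime is questionable there).
#' @param dna_copies integer number of promoter copies.
#' @return an object of class `detailed_switch_params`.
#' @seealso [ssa_detailed()]
#' @export
detailed_switch_params <- function(a = 0.1, b = 2, h = 2, Omega = 50,
                                   keq = 1, koff = 100, dna_copies = 1L) {
  p <- hill_switch_params(a = a, b = b, h = h, Omega = Omega)
  stopifnot(is.numeric(keq), length(keq) == 1L, is.finite(keq),
            is.numeric(koff), length(koff) == 1L, is.finite(koff),
            length(dna_copies) == 1L)
  if (keq <= 0) stop("'keq' must be > 0")
  if (koff <= 0) stop("'koff' must be > 0")
  if (dna_copies < 1 || dna_copies != round(dna_copies))
    stop("'dna_copies' must be a positive integer")
  if (koff < 10)
    warning("koff < 10: promoter kinetics are not fast; ",
            "the quasi-steady-state reduction to the Hill switch may fail")
  structure(c(unclass(p), list(keq = keq, koff = koff,
                               dna_copies = as.integer(dna_copies))),
            class = "detailed_switch_params")
}

#' Hill production rate of the auto-activating switch
#'
#' Evaluates `g(x) = a + b * x^h / (1 + x^h)`, the dimensionless production
#' rate of the auto-activating switch. Strictly increasing in `x` for
#' `b > 0`, with `g(0) = a` and saturation at `a + b`.
#'
#' @param x concentration(s), `x >= 0`.
#' @param p parameter record with fields `a`, `b`, `h` (e.g. from
#'   [hill_switch_params()]).
#' @return production rate(s), same length as `x`.
#' @export
hill_g <- function(x, p) {
  if (any(x < 0)) stop("negative concentration: 'x' must be >= 0")
  xh <- x^p$h
  p$a + p$b * xh / (1 + xh)
}

## ---------------------------------------------------------------------------
## Closed-form derivatives of the Hill function H(x) = x^h / (1 + x^h)
## ---------------------------------------------------------------------------

# Symbolic derivative chain built once: .hill_exprs[[k+1]] is d^k/dx^k H(x).
.hill_exprs <- local({
  e <- quote(x^h / (1 + x^h))
  out <- vector("list", 5L)
  out[[1L]] <- e
  for (k in 1:4) {
    e <- D(e, "x")
    out[[k + 1L]] <- e
  }
  out
})

# k-th derivative of H(x) = x^h/(1+x^h), vectorized in x; exact limits at
# x = 0 via the series H = sum_m (-1)^(m+1) x^(mh) (the symbolic expressions
# hit 0 * Inf there for some (h, k)).
hill_H_deriv <- function(x, h, k = 0L) {
  val <- eval(.hill_exprs[[k + 1L]], list(x = x, h = h))
  val <- rep_len(val, length(x))
  bad <- !is.finite(val) | x < 1e-12
  if (any(bad)) {
    xb <- x[bad]
    acc <- numeric(length(xb))
    m_max <- ceiling((k + 12) / h)
    for (m in seq_len(m_max)) {
      pw <- m * h - k
      if (pw < 0) next
      cf <- (-1)^(m + 1) * prod(seq.int(m * h, by = -1, length.out = k))
      if (k == 0L) cf <- (-1)^(m + 1)
      acc <- acc + cf * ifelse(pw == 0, 1, xb^pw)
    }
    val[bad] <- acc
  }
  val
}

## ---------------------------------------------------------------------------
## Regulatory models
## ---------------------------------------------------------------------------

#' Construct a regulatory model
#'
#' A regulatory model packages the gene regulatory (production) function
#' `g(x, b)` together with its partial derivatives in the state `x` and the
#' control parameter `b`, for the class of one-variable birth-death circuits
#' with production `g` and linear degradation at rate 1. Derivatives are
#' needed up to fourth order in `x` by the perturbative machinery; supply
#' them in closed form via `dg` when available, otherwise central finite
#' differences are used (step scaled with the derivative order to balance
#' truncation against round-off).
#'
#' @param g function of `(x, b)` returning the production rate; must be
#'   non-negative for `x >= 0`.
#' @param dg optional function `(x, b, ix, ib)` returning the partial
#'   derivative of `g` of order `ix` in `x` and `ib` in `b`.
#' @param kind short label (e.g. `"hill"`); the simulation engines use it to
#'   select compiled fast paths.
#' @param params named list of model constants.
#' @param b_range plausible range of the control parameter, used to bracket
#'   bifurcation points.
#' @param fp_poly optional function of `b` returning polynomial coefficients
#'   (increasing order) whose real non-negative roots are the fixed points of
#'   `g(x, b) - x`; enables companion-matrix root finding.
#' @return an object of class `regulatory_model`.
#' @export
regulatory_model <- function(g, dg = NULL, kind = "custom", params = list(),
                             b_range = c(0, 10), fp_poly = NULL) {
  stopifnot(is.function(g), is.null(dg) || is.function(dg),
            is.numeric(b_range), length(b_range) == 2L,
            b_range[1] < b_range[2])
  if (is.null(dg)) dg <- fd_deriv_factory(g)
  structure(list(g = g, dg = dg, kind = kind, params = params,
                 deg_rate = 1, b_range = b_range, fp_poly = fp_poly),
            class = "regulatory_model")
}

#' @export
print.regulatory_model <- function(x, ...) {
  cat("<regulatory_model>", x$kind, "\n")
  if (length(x$params))
    cat("  params:", paste(names(x$params), unlist(x$params), sep = " = ",
                           collapse = ", "), "\n")
  cat("  degradation rate: 1 (dimensionless units)\n")
  cat("  b range: [", x$b_range[1], ",", x$b_range[2], "]\n")
  invisible(x)
}

# Finite-difference derivative closure for user-supplied g without analytic
# derivatives. Central stencils; step grows with the x-order (h ~ eps^(1/(k+2)))
# so that round-off does not swamp the high-order stencils.
fd_deriv_factory <- function(g) {
  stencil <- list(
    list(o = c(-1, 1),          w = c(-1/2, 1/2)),
    list(o = c(-1, 0, 1),       w = c(1, -2, 1)),
    list(o = c(-2, -1, 1, 2),   w = c(-1/2, 1, -1, 1/2)),
    list(o = c(-2, -1, 0, 1, 2), w = c(1, -4, 6, -4, 1))
  )
  step_x <- c(6e-6, 1.3e-4, 8e-4, 2.5e-3)
  dx <- function(x, b, k) {
    if (k == 0L) return(g(x, b))
    st <- stencil[[k]]
    hh <- step_x[k] * max(1, abs(x))
    sum(st$w * vapply(st$o, function(o) g(x + o * hh, b), numeric(1))) / hh^k
  }
  function(x, b, ix = 0L, ib = 0L) {
    if (ib == 0L) return(dx(x, b, ix))
    hb <- 6e-6 * max(1, abs(b))
    if (ib == 1L)
      return((dx(x, b + hb, ix) - dx(x, b - hb, ix)) / (2 * hb))
    hb <- 1.3e-4 * max(1, abs(b))
    if (ib == 2L)
      return((dx(x, b + hb, ix) - 2 * dx(x, b, ix) + dx(x, b - hb, ix)) / hb^2)
    stop("b-derivatives beyond order 2 are not supported")
  }
}

#' Auto-activating Hill switch model
#'
#' The reference bistable circuit: `g(x, b) = a + b * x^h / (1 + x^h)`. The
#' control parameter `b` (maximum production rate) promotes production, so
#' noise delays its saddle-node bifurcations (positive first-order shift).
#' All derivatives are closed-form.
#'
#' @param a basal expression rate, `a > 0`.
#' @param h cooperativity, positive integer.
#' @param b_range bracketing range for the control parameter.
#' @return a `regulatory_model` with `kind = "hill"`.
#' @examples
#' m <- hill_activator(a = 0.1, h = 2)
#' deterministic_bifurcation_points(m)
#' @export
hill_activator <- function(a = 0.1, h = 2, b_range = c(0, 10)) {
  stopifnot(a > 0, h >= 1, h == round(h))
  h <- as.integer(h)
  g <- function(x, b) a + b * hill_H_deriv(x, h, 0L)
  dg <- function(x, b, ix = 0L, ib = 0L) {
    if (ib == 0L) {
      v <- b * hill_H_deriv(x, h, ix)
      if (ix == 0L) v <- v + a
      v
    } else if (ib == 1L) {
      hill_H_deriv(x, h, ix)
    } else {
      0 * x  # g is linear in b
    }
  }
  fp_poly <- function(b) hill_fp_poly(a, b, h)
  regulatory_model(g, dg, kind = "hill", params = list(a = a, h = h),
                   b_range = b_range, fp_poly = fp_poly)
}

#' Hill switch with an inhibitory control parameter
#'
#' A bistable Hill circuit in which the control parameter suppresses the
#' positive-feedback strength: `g(x, b) = a + (c - b) * x^h / (1 + x^h)` for
#' `0 <= b <= c`. Because `dg/db < 0` (the parameter inhibits production),
#' noise advances the saddle-node bifurcations: the first-order shift
#' coefficient `b1` is negative, the mirror image of [hill_activator()].
#'
#' @inheritParams hill_activator
#' @param c fixed maximal feedback strength; the effective activation is
#'   `c - b`.
#' @return a `regulatory_model` with `kind = "hill_inhibitor"`.
#' @export
hill_inhibitor <- function(a = 0.1, h = 2, c = 4) {
  stopifnot(a > 0, h >= 1, h == round(h), c > 0)
  h <- as.integer(h)
  g <- function(x, b) a + (c - b) * hill_H_deriv(x, h, 0L)
  dg <- function(x, b, ix = 0L, ib = 0L) {
    if (ib == 0L) {
      v <- (c - b) * hill_H_deriv(x, h, ix)
      if (ix == 0L) v <- v + a
      v
    } else if (ib == 1L) {
      -hill_H_deriv(x, h, ix)
    } else {
      0 * x
    }
  }
  fp_poly <- function(b) hill_fp_poly(a, c - b, h)
  regulatory_model(g, dg, kind = "hill_inhibitor",
                   params = list(a = a, h = h, c = c),
                   b_range = c(0, c), fp_poly = fp_poly)
}

# Polynomial (increasing order) whose real non-negative roots solve
# g(x) = x for the Hill family: x^(h+1) - (a + beff) x^h + x - a = 0.
hill_fp_poly <- function(a, beff, h) {
  cf <- numeric(h + 2L)
  cf[1L] <- -a
  cf[2L] <- cf[2L] + 1
  cf[h + 1L] <- cf[h + 1L] - (a + beff)
  cf[h + 2L] <- cf[h + 2L] + 1
  cf
}

## ---------------------------------------------------------------------------
## Langevin specification
## ---------------------------------------------------------------------------

#' Build the chemical Langevin specification of a regulatory model
#'
#' For a one-variable birth-death circuit with production `g(x, b)` and
#' degradation `x`, the Ito chemical Langevin equation is
#' `dx = f(x, b) dt + epsilon * sqrt(B(x, b)) dW` with drift
#' `f = g - x`, diffusion shape `B = g + x` (sum of the two propensities),
#' and noise intensity `epsilon = Omega^(-1/2)` set by the cell volume.
#'
#' @param model a [regulatory_model()].
#' @param Omega dimensionless cell volume, `Omega > 0`.
#' @return an object of class `langevin_spec` with elements `drift(x, b)`,
#'   `diffusion_shape(x, b)`, `epsilon`, `Omega` and the model.
#' @examples
#' spec <- build_langevin(hill_activator(), Omega = 100)
#' spec$epsilon  # 0.1
#' @export
build_langevin <- function(model, Omega) {
  stopifnot(inherits(model, "regulatory_model"))
  if (!is.numeric(Omega) || length(Omega) != 1L || !is.finite(Omega) ||
      Omega <= 0)
    stop("'Omega' must be a positive finite number")
  structure(list(
    drift = function(x, b) model$g(x, b) - x,
    diffusion_shape = function(x, b) model$g(x, b) + x,
    epsilon = 1 / sqrt(Omega),
    Omega = Omega,
    model = model
  ), class = "langevin_spec")
}

#' Langevin specification from arbitrary drift and diffusion
#'
#' Escape hatch for systems outside the production-degradation class (for
#' which [build_langevin()] is the natural constructor): any Ito equation
#' `dx = f(x, b) dt + epsilon * sqrt(B(x, b)) dW`. Such specs support the
#' stationary density, its extrema and the simulation engines (pure-R path);
#' operations needing control-parameter derivatives of a regulatory model
#' (perturbation, continuation) require [build_langevin()].
#'
#' @param drift function `(x, b) -> f(x, b)`.
#' @param diffusion_shape function `(x, b) -> B(x, b)`, positive on the
#'   working domain.
#' @param epsilon noise intensity (`> 0`).
#' @return an object of class `langevin_spec` with `model = NULL`.
#' @export
langevin_custom <- function(drift, diffusion_shape, epsilon) {
  stopifnot(is.function(drift), is.function(diffusion_shape), epsilon > 0)
  structure(list(drift = drift, diffusion_shape = diffusion_shape,
                 epsilon = epsilon, Omega = 1 / epsilon^2, model = NULL),
            class = "langevin_spec")
}

#' @export
print.langevin_spec <- function(x, ...) {
  cat("<langevin_spec> dx = f dt + eps * sqrt(B) dW (Ito)\n")
  cat("  Omega =", x$Omega, " epsilon =", format(x$epsilon, digits = 6), "\n")
  if (!is.null(x$model)) print(x$model) else cat("  custom drift/diffusion\n")
  invisible(x)
}

# Partial derivatives of drift f = g - x and diffusion shape B = g + x.
spec_f_deriv <- function(model, x, b, ix = 0L, ib = 0L) {
  v <- model$dg(x, b, ix, ib)
  if (ib == 0L) {
    if (ix == 0L) v <- v - x
    if (ix == 1L) v <- v - 1
  }
  v
}
spec_B_deriv <- function(model, x, b, ix = 0L, ib = 0L) {
  v <- model$dg(x, b, ix, ib)
  if (ib == 0L) {
    if (ix == 0L) v <- v + x
    if (ix == 1L) v <- v + 1
  }
  v
}

## ---------------------------------------------------------------------------
## Deterministic fixed points and saddle-node bifurcations
## ---------------------------------------------------------------------------

#' Deterministic fixed points of a regulatory model
#'
#' All real non-negative roots of `g(x, b) - x = 0`, sorted ascending. For
#' Hill-family models the equation is converted to polynomial form and solved
#' by companion-matrix root finding ([polyroot()]); otherwise roots are
#' isolated by a sign scan and refined by [uniroot()]. Every root is polished
#' by Newton iteration to residual below `1e-12`.
#'
#' @param b control parameter value, `b >= 0` (or within the model's range).
#' @param model a [regulatory_model()].
#' @return numeric vector of fixed points (length 1 or 3; 2 exactly at a
#'   saddle-node).
#' @export
deterministic_fixed_points <- function(b, model) {
  stopifnot(inherits(model, "regulatory_model"), is.numeric(b),
            length(b) == 1L, is.finite(b))
  if (!is.null(model$fp_poly)) {
    cf <- model$fp_poly(b)
    z <- polyroot(cf)
    x <- Re(z)[abs(Im(z)) < 1e-9 & Re(z) > -1e-12]
    x <- pmax(x, 0)
  } else {
    x <- fp_scan(model, b)
  }
  x <- sort(newton_polish_fp(model, x, b))
  # drop duplicates closer than root-finding noise
  if (length(x) > 1L) x <- x[c(TRUE, diff(x) > 1e-8)]
  x
}

# Sign-scan root isolation for models without a polynomial form.
fp_scan <- function(model, b, n_grid = 2000L) {
  x_hi <- 1
  for (i in 1:60) {
    g_hi <- model$g(x_hi, b)
    if (x_hi > g_hi + 1) break
    x_hi <- x_hi * 2
  }
  xs <- seq(0, x_hi, length.out = n_grid)
  fs <- model$g(xs, b) - xs
  idx <- which(fs[-length(fs)] * fs[-1L] <= 0 & fs[-length(fs)] != 0)
  roots <- vapply(idx, function(i) {
    uniroot(function(x) model$g(x, b) - x, c(xs[i], xs[i + 1L]),
            tol = 1e-12)$root
  }, numeric(1))
  exact <- xs[fs == 0]
  sort(unique(c(roots, exact)))
}

newton_polish_fp <- function(model, x, b, tol = 1e-13, maxit = 60L) {
  vapply(x, function(r) {
    for (i in seq_len(maxit)) {
      f <- model$g(r, b) - r
      if (abs(f) < tol) break
      fp <- model$dg(r, b, 1L, 0L) - 1
      if (!is.finite(fp) || abs(fp) < 1e-14) break
      step <- f / fp
      # do not let polishing jump to a different root
      if (abs(step) > 0.1 * max(1, abs(r))) step <- sign(step) * 0.1 * max(1, abs(r))
      r <- r - step
    }
    max(r, 0)
  }, numeric(1))
}

#' A located bifurcation point
#'
#' Small record class for a saddle-node (fold) point `(b_star, x_star)` of a
#' regulatory model, labelled by branch (`"lower"`/`"upper"`, ordered by
#' `b_star`) and by the method that produced it.
#'
#' @param b_star control-parameter value of the fold.
#' @param x_star state value at the fold.
#' @param branch `"lower"` or `"upper"`.
#' @param method one of `"deterministic"`, `"perturbative"`,
#'   `"continuation"`, `"exact_master"`, `"simulation"`.
#' @param ... extra fields (e.g. `order`, `epsilon`, `residual`).
#' @return an object of class `bifurcation_point`.
#' @export
bifurcation_point <- function(b_star, x_star, branch, method, ...) {
  stopifnot(branch %in% c("lower", "upper"))
  structure(list(b_star = b_star, x_star = x_star, branch = branch,
                 method = method, ...),
            class = "bifurcation_point")
}

#' @export
print.bifurcation_point <- function(x, ...) {
  cat(sprintf("<bifurcation_point> %s branch [%s]: b* = %.10g, x* = %.10g\n",
              x$branch, x$method, x$b_star, x$x_star))
  if (!is.null(x$epsilon)) cat("  epsilon =", x$epsilon, "\n")
  invisible(x)
}

#' Deterministic saddle-node bifurcation points
#'
#' Locates the two fold points of a bistable regulatory model, i.e. the
#' simultaneous solutions of `f(x, b) = 0` and `df/dx(x, b) = 0` with
#' `f = g - x`. The control-parameter range is scanned for changes in the
#' number of fixed points; each transition seeds a damped 2-D Newton solve of
#' the fold conditions, converged to residuals below `1e-12`.
#'
#' @param model a [regulatory_model()].
#' @param b_range range of the control parameter to scan; defaults to the
#'   model's own range.
#' @param n_scan number of scan points.
#' @return a list of class `bifurcation_points` with elements `bistable`
#'   (logical), and when bistable, `lower` and `upper`
#'   ([bifurcation_point()] records with `b_star` ordered). When no bistable
#'   window exists the result has `bistable = FALSE` (no error is thrown).
#' @export
deterministic_bifurcation_points <- function(model,
                                             b_range = model$b_range,
                                             n_scan = 600L) {
  stopifnot(inherits(model, "regulatory_model"))
  bs <- seq(b_range[1], b_range[2], length.out = n_scan)
  counts <- vapply(bs, function(b) length(deterministic_fixed_points(b, model)),
                   integer(1))
  trans <- which(diff(counts) != 0L)
  if (!length(trans))
    return(structure(list(bistable = FALSE,
                          reason = "fixed-point count constant over b_range"),
                     class = "bifurcation_points"))
  pts <- list()
  for (i in trans) {
    lo <- bs[i]; hi <- bs[i + 1L]
    c_lo <- counts[i]
    # bisect to a tight bracket around the fold
    for (k in 1:40) {
      mid <- (lo + hi) / 2
      c_mid <- length(deterministic_fixed_points(mid, model))
      if (c_mid == c_lo) lo <- mid else hi <- mid
    }
    # seed x at the closest pair of roots on the 3-root side
    b_three <- if (counts[i] > counts[i + 1L]) lo else hi
    r <- deterministic_fixed_points(b_three, model)
    if (length(r) >= 2L) {
      j <- which.min(diff(r))
      x_seed <- (r[j] + r[j + 1L]) / 2
    } else x_seed <- r[1L]
    sol <- fold_newton(model, x_seed, (lo + hi) / 2)
    if (!is.null(sol)) pts[[length(pts) + 1L]] <- sol
  }
  if (!length(pts))
    return(structure(list(bistable = FALSE,
                          reason = "fold refinement failed at every transition"),
                     class = "bifurcation_points"))
  b_vals <- vapply(pts, `[[`, numeric(1), "b_star")
  # dedupe folds found from both sides of a transition
  keep <- !duplicated(round(b_vals, 8))
  pts <- pts[keep]; b_vals <- b_vals[keep]
  if (length(pts) != 2L)
    return(structure(list(bistable = FALSE,
                          reason = sprintf("found %d folds, expected 2",
                                           length(pts)),
                     points = pts), class = "bifurcation_points"))
  o <- order(b_vals)
  lower <- pts[[o[1L]]]; upper <- pts[[o[2L]]]
  lower$branch <- "lower"; upper$branch <- "upper"
  structure(list(bistable = TRUE, lower = lower, upper = upper),
            class = "bifurcation_points")
}

#' @export
print.bifurcation_points <- function(x, ...) {
  if (!x$bistable) {
    cat("<bifurcation_points> no bistable region:", x$reason, "\n")
  } else {
    cat("<bifurcation_points> bistable window b in (",
        format(x$lower$b_star, digits = 10), ",",
        format(x$upper$b_star, digits = 10), ")\n")
    print(x$lower); print(x$upper)
  }
  invisible(x)
}

# Damped Newton on the fold system (f, f_x) = 0 in (x, b).
fold_newton <- function(model, x0, b0, tol = 1e-12, maxit = 100L) {
  x <- x0; b <- b0
  for (i in seq_len(maxit)) {
    f  <- spec_f_deriv(model, x, b, 0L, 0L)
    fx <- spec_f_deriv(model, x, b, 1L, 0L)
    if (max(abs(f), abs(fx)) < tol && i > 1L)
      return(bifurcation_point(b, x, branch = "lower",
                               method = "deterministic",
                               residual = max(abs(f), abs(fx))))
    fb  <- spec_f_deriv(model, x, b, 0L, 1L)
    fxx <- spec_f_deriv(model, x, b, 2L, 0L)
    fxb <- spec_f_deriv(model, x, b, 1L, 1L)
    det <- fx * fxb - fb * fxx
    if (!is.finite(det) || abs(det) < 1e-16) return(NULL)
    # solve [[fx, fb], [fxx, fxb]] * (dx, db) = (f, fx)
    dx <- ( fxb * f - fb * fx) / det
    db <- (-fxx * f + fx * fx) / det
    # damp large steps
    sc <- max(1, abs(dx) / (0.2 * max(1, abs(x))), abs(db) / (0.2 * max(1, abs(b))))
    x <- x - dx / sc
    b <- b - db / sc
    if (x < 0) x <- 1e-12
  }
  f  <- spec_f_deriv(model, x, b, 0L, 0L)
  fx <- spec_f_deriv(model, x, b, 1L, 0L)
  if (max(abs(f), abs(fx)) < tol)
    return(bifurcation_point(b, x, branch = "lower", method = "deterministic",
                             residual = max(abs(f), abs(fx))))
  NULL
}
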