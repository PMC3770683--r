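## Perturbative expansion of the stochastic bifurcation points in powers of
## the noise intensity s = epsilon^2, including the long-correlation-time
## (colored noise) limit.

# All coefficients are obtained from the implicit series solution of
#   F(x, b, s)   = f - (s/2) B_x  = 0
#   F_x(x, b, s) = f_x - (s/2) B_xx = 0
# around the deterministic saddle-node (x0, b0) where f = f_x = 0.
# Substituting x = x0 + s x1 + s^2 x2, b = b0 + s b1 + s^2 b2 and collecting
# powers of s:
#   s^1 of F:    f_b b1 - B_x/2 = 0                       (f_x = 0 at the fold)
#   s^1 of F_x:  f_xx x1 + f_xb b1 - B_xx/2 = 0
#   s^2 of F:    f_b b2 + f_xx x1^2/2 + f_xb x1 b1 + f_bb b1^2/2
#                - (B_xx x1 + B_xb b1)/2 = 0
#   s^2 of F_x:  f_xx x2 + f_xb b2 + f_xxx x1^2/2 + f_xxb x1 b1
#                + f_xbb b1^2/2 - (B_xxx x1 + B_xxb b1)/2 = 0
# All derivatives are evaluated at (x0, b0).

saddle_node_env <- function(model, branch) {
  det <- deterministic_bifurcation_points(model)
  if (!det$bistable)
    stop("model has no deterministic bistable region; ",
         "the expansion point (saddle-node) does not exist")
  pt <- det[[branch]]
  x0 <- pt$x_star; b0 <- pt$b_star
  d <- function(fun, ix, ib) fun(model, x0, b0, ix, ib)
  env <- list(
    x0 = x0, b0 = b0,
    f_b   = d(spec_f_deriv, 0L, 1L),
    f_xx  = d(spec_f_deriv, 2L, 0L),
    f_xb  = d(spec_f_deriv, 1L, 1L),
    f_bb  = d(spec_f_deriv, 0L, 2L),
    f_xxx = d(spec_f_deriv, 3L, 0L),
    f_xxb = d(spec_f_deriv, 2L, 1L),
    f_xbb = d(spec_f_deriv, 1L, 2L),
    B_x   = d(spec_B_deriv, 1L, 0L),
    B_xx  = d(spec_B_deriv, 2L, 0L),
    B_xb  = d(spec_B_deriv, 1L, 1L),
    B_xxx = d(spec_B_deriv, 3L, 0L),
    B_xxb = d(spec_B_deriv, 2L, 1L)
  )
  if (abs(env$f_b) < 1e-12)
    stop("degenerate expansion point: df/db vanishes at the saddle-node ",
         "(codimension-2 point)")
  if (abs(env$f_xx) < 1e-12)
    stop("degenerate expansion point: d2f/dx2 vanishes at the saddle-node ",
         "(cusp/codimension-2 point)")
  env
}

#' First-order noise-induced shift of a saddle-node bifurcation
#'
#' At order one in the noise intensity `s = epsilon^2`, the stochastic
#' bifurcation point sits at `b* = b0 + s * b1`, `x* = x0 + s * x1` with
#' `b1 = B_x / (2 f_b)` and `x1 = (B_xx/2 - f_xb b1) / f_xx`, all evaluated
#' at the deterministic saddle-node `(x0, b0)`. At the fold `df/dx = 0`
#' implies `dg/dx = 1` and hence `B_x = 2`, so `sign(b1) = sign(dg/db)`: a
#' control parameter that promotes production (activator) delays the
#' bifurcation (`b1 > 0`); one that inhibits production advances it
#' (`b1 < 0`).
#'
#' @param model a [regulatory_model()] with a deterministic bistable window.
#' @param branch `"lower"` or `"upper"` saddle-node.
#' @return a list with `b1`, `x1` and the expansion point `b0`, `x0`.
#' @seealso [shift_series()] for the order-2 extension,
#'   [colored_longtau_shift()] for the long-correlation-time limit.
#' @export
shift_first_order <- function(model, branch = c("lower", "upper")) {
  branch <- match.arg(branch)
  e <- saddle_node_env(model, branch)
  b1 <- e$B_x / (2 * e$f_b)
  x1 <- (e$B_xx / 2 - e$f_xb * b1) / e$f_xx
  list(b1 = b1, x1 = x1, b0 = e$b0, x0 = e$x0, branch = branch)
}

#' Perturbative series of a stochastic bifurcation point
#'
#' Expansion of the stochastic bifurcation point in powers of the noise
#' intensity `s = epsilon^2`:
#' `b*(s) = b0 + b1 s + b2 s^2`, `x*(s) = x0 + x1 s + x2 s^2`.
#' Order 0 is the deterministic saddle-node; orders 1 and 2 are obtained by
#' substituting the series into the extremum-fold conditions
#' `F = f - (s/2) dB/dx = 0`, `dF/dx = 0` and collecting powers of `s`
#' (each order yields a linear 2x2 system).
#'
#' @inheritParams shift_first_order
#' @param order expansion order: 0, 1 or 2.
#' @param noise_kind `"white"` for the Ito chemical Langevin equation;
#'   `"colored_long_tau"` for the long-correlation-time limit of an
#'   Ornstein-Uhlenbeck drive, in which the effective noise intensity is
#'   halved (all shift coefficients are half their white-noise values).
#' @return an object of class `shift_series` with fields `branch`, `order`,
#'   `noise_kind`, `b_coeffs` and `x_coeffs` (length `order + 1`, constant
#'   term first, coefficients of `s^k`).
#' @examples
#' m <- hill_activator()
#' s2 <- shift_series(m, "upper", order = 2)
#' predict_shift(s2, epsilon = 0.1)
#' @export
shift_series <- function(model, branch = c("lower", "upper"), order = 2L,
                         noise_kind = c("white", "colored_long_tau")) {
  branch <- match.arg(branch)
  noise_kind <- match.arg(noise_kind)
  stopifnot(order %in% 0:2)
  e <- saddle_node_env(model, branch)
  b_coeffs <- e$b0
  x_coeffs <- e$x0
  if (order >= 1L) {
    b1 <- e$B_x / (2 * e$f_b)
    x1 <- (e$B_xx / 2 - e$f_xb * b1) / e$f_xx
    b_coeffs <- c(b_coeffs, b1)
    x_coeffs <- c(x_coeffs, x1)
  }
  if (order >= 2L) {
    b2 <- -(e$f_xx * x1^2 / 2 + e$f_xb * x1 * b1 + e$f_bb * b1^2 / 2 -
              (e$B_xx * x1 + e$B_xb * b1) / 2) / e$f_b
    x2 <- -(e$f_xb * b2 + e$f_xxx * x1^2 / 2 + e$f_xxb * x1 * b1 +
              e$f_xbb * b1^2 / 2 - (e$B_xxx * x1 + e$B_xxb * b1) / 2) / e$f_xx
    b_coeffs <- c(b_coeffs, b2)
    x_coeffs <- c(x_coeffs, x2)
  }
  if (noise_kind == "colored_long_tau" && order >= 1L) {
    # long-tau limit: same fold conditions with the noise intensity halved,
    # i.e. s -> s/2 in the series
    k <- seq_along(b_coeffs) - 1L
    b_coeffs <- b_coeffs / 2^k
    x_coeffs <- x_coeffs / 2^k
  }
  if (!all(is.finite(c(b_coeffs, x_coeffs))))
    stop("non-finite expansion coefficients (degenerate saddle-node?)")
  structure(list(branch = branch, order = as.integer(order),
                 noise_kind = noise_kind,
                 b_coeffs = b_coeffs, x_coeffs = x_coeffs),
            class = "shift_series")
}

#' @export
print.shift_series <- function(x, ...) {
  cat("<shift_series>", x$branch, "branch,", x$noise_kind,
      "noise, order", x$order, "(powers of s = epsilon^2)\n")
  cat("  b*:", paste(format(x$b_coeffs, digits = 8), collapse = " + s*"), "\n")
  cat("  x*:", paste(format(x$x_coeffs, digits = 8), collapse = " + s*"), "\n")
  invisible(x)
}

#' Evaluate a perturbative shift series at a noise intensity
#'
#' @param series a [shift_series()].
#' @param epsilon noise intensity (`s = epsilon^2`).
#' @return a [bifurcation_point()] with `method = "perturbative"` and field
#'   `order`.
#' @export
predict_shift <- function(series, epsilon) {
  stopifnot(inherits(series, "shift_series"), epsilon >= 0)
  s <- epsilon^2
  pw <- s^(seq_along(series$b_coeffs) - 1L)
  bifurcation_point(sum(series$b_coeffs * pw), sum(series$x_coeffs * pw),
                    branch = series$branch, method = "perturbative",
                    order = series$order, epsilon = epsilon,
                    noise_kind = series$noise_kind)
}

#' Long-correlation-time (colored noise) first-order shift
#'
#' When the driving fluctuations are an Ornstein-Uhlenbeck process with long
#' correlation time, the bifurcation conditions are those of the white-noise
#' case with the noise intensity halved, so the first-order corrections are
#' exactly half the white-noise ones: `b1_colored = b1_white / 2`,
#' `x1_colored = x1_white / 2`. The shift is lessened but keeps its sign.
#'
#' @inheritParams shift_first_order
#' @return a list with `b1`, `x1` (colored), the white-noise values
#'   `b1_white`, `x1_white`, and the expansion point.
#' @export
colored_longtau_shift <- function(model, branch = c("lower", "upper")) {
  branch <- match.arg(branch)
  w <- shift_first_order(model, branch)
  list(b1 = w$b1 / 2, x1 = w$x1 / 2,
       b1_white = w$b1, x1_white = w$x1,
       b0 = w$b0, x0 = w$x0, branch = branch)
}

#' Export a shift series as JSON
#'
#' Writes `{branch, noise_kind, order, b_coeffs, x_coeffs}`.
#'
#' @param series a [shift_series()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_shift_series_json <- function(series, path) {
  stopifnot(inherits(series, "shift_series"))
  jsonlite::write_json(unclass(series), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
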