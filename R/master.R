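## Exact stationary solution of the one-step birth-death master equation by
## detailed balance, and discrete mode analysis.

#' Exact stationary distribution of the birth-death master equation
#'
#' The regulatory circuit with production `g` and linear degradation is a
#' one-step birth-death process on molecule counts `n`, with birth rate
#' `W+(n) = Omega * g(n / Omega, b)` and death rate `W-(n) = n` (degradation
#' rate 1 in dimensionless units). Detailed balance at stationarity gives the
#' exact product form
#' `Ps(n) = Ps(0) * prod_{m=1..n} W+(m - 1) / m`,
#' which is accumulated in log space and normalized. The truncation `n_max`
#' is auto-extended (doubling) until the probability at the boundary is below
#' `1e-10` of the peak and the flux ratio at the boundary is contracting.
#'
#' @param model a [regulatory_model()].
#' @param b control parameter value.
#' @param Omega dimensionless cell volume (`> 0`).
#' @param n_max initial truncation; default `ceil(10 * Omega * g_sat) + 50`
#'   where `g_sat` is the production rate at saturation.
#' @param n_cap hard cap on the truncation (error if exceeded).
#' @return an object of class `discrete_distribution`: list with `n`
#'   (`0:n_max`), `probs` (normalized), `logp`, `Omega`, `b`.
#' @examples
#' m <- hill_activator()
#' d <- birth_death_stationary(m, b = 2.2, Omega = 12.5)
#' discrete_modes(d)
#' @export
birth_death_stationary <- function(model, b, Omega, n_max = NULL,
                                   n_cap = 1e6) {
  stopifnot(inherits(model, "regulatory_model"))
  if (Omega <= 0) stop("'Omega' must be > 0")
  if (is.null(n_max)) {
    g_sat <- max(model$g(c(0, 10^(0:6)), b))
    n_max <- ceiling(10 * Omega * max(g_sat, 0.1)) + 50
  }
  repeat {
    m <- seq_len(n_max)
    wplus <- Omega * model$g((m - 1) / Omega, b)  # W+(m-1), m = 1..n_max
    if (any(wplus < 0)) stop("negative birth rate: g must be non-negative")
    logp <- c(0, cumsum(log(wplus) - log(m)))
    logZ <- logsumexp(logp)
    logp <- logp - logZ
    peak <- max(logp)
    contracting <- Omega * model$g(n_max / Omega, b) / (n_max + 1) < 1
    if (logp[n_max + 1L] - peak < log(1e-10) && contracting) break
    if (n_max >= n_cap)
      stop("truncation cap reached (n_max = ", n_max,
           ") without meeting the tail criterion")
    n_max <- min(2 * n_max, n_cap)
  }
  structure(list(n = 0:n_max, probs = exp(logp), logp = logp,
                 Omega = Omega, b = b),
            class = "discrete_distribution")
}

#' @export
print.discrete_distribution <- function(x, ...) {
  cat("<discrete_distribution> n = 0 ..", max(x$n),
      " (Omega =", x$Omega, ", b =", x$b, ")\n")
  md <- discrete_modes(x)
  cat("  modes at n =", paste(md, collapse = ", "),
      " (x = n/Omega:", paste(format(md / x$Omega, digits = 5),
                              collapse = ", "), ")\n")
  invisible(x)
}

#' Modes of a discrete distribution
#'
#' Local maxima of `Ps(n)`: a strict rise followed by a strict fall, with
#' plateaus resolved to their smallest `n`. Boundary modes (at `n = 0` for a
#' decreasing distribution, or at the truncation edge) are included. Used to
#' classify the exact birth-death system as unimodal or bimodal.
#'
#' @param dist a [birth_death_stationary()] result (or any list with fields
#'   `n` and `probs`).
#' @return integer vector of mode locations (counts `n`), ascending.
#' @export
discrete_modes <- function(dist) {
  p <- dist$probs
  n <- dist$n
  # compress plateaus to their first index
  keep <- c(TRUE, diff(p) != 0)
  pc <- p[keep]; nc <- n[keep]
  k <- length(pc)
  if (k == 1L) return(nc[1L])
  rise <- c(TRUE, diff(pc) > 0)   # treat the left boundary as rising into it
  fall <- c(diff(pc) < 0, TRUE)   # and the right boundary as falling after it
  nc[rise & fall]
}

#' Detailed-balance residual of a discrete distribution
#'
#' Maximum relative violation of `W+(n) Ps(n) = W-(n+1) Ps(n+1)` over the
#' support; by construction of the product-form solution this is at the level
#' of floating-point round-off.
#'
#' @param dist a [birth_death_stationary()] result.
#' @param model the [regulatory_model()] it was built from.
#' @return the maximum relative residual (scalar).
#' @export
detailed_balance_residual <- function(dist, model) {
  n <- dist$n
  p <- dist$probs
  keep <- p[-length(p)] > 1e-300
  up <- dist$Omega * model$g(n[-length(n)] / dist$Omega, dist$b) * p[-length(p)]
  down <- n[-1] * p[-1]
  r <- abs(up - down) / pmax(abs(up), abs(down), 1e-300)
  max(r[keep & p[-1] > 1e-300], 0)
}

#' Export a discrete distribution as CSV
#'
#' Writes columns `n`, `prob`.
#'
#' @param dist a `discrete_distribution`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_distribution_csv <- function(dist, path) {
  stopifnot(inherits(dist, "discrete_distribution"))
  write.csv(data.frame(n = dist$n, prob = dist$probs), path,
            row.names = FALSE)
  invisible(path)
}
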