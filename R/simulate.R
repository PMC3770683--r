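## Simulation engines: Euler-Maruyama (Ito), colored-noise Heun integrator
## driven by an exact Ornstein-Uhlenbeck update, and Gillespie SSA for the
## simple and detailed switch models. Hill-family models dispatch to compiled
## engines; arbitrary regulatory models fall back to a pure-R integrator.

new_trajectory <- function(times, states, seed, engine, params,
                           record = "grid", d1 = NULL, n_events = NULL) {
  structure(list(times = times, states = states, d1 = d1, seed = seed,
                 engine = engine, params = params, record = record,
                 n_events = n_events),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory>", x$engine, " seed =", x$seed, "\n")
  cat("  ", length(x$times), "samples on t in [0,",
      format(max(x$times), digits = 6), "], recording:", x$record, "\n")
  if (!is.null(x$n_events)) cat("  events:", format(x$n_events), "\n")
  invisible(x)
}

# effective Hill activation strength, or NULL when no compiled fast path
hill_beff <- function(model, b) {
  if (identical(model$kind, "hill")) return(b)
  if (identical(model$kind, "hill_inhibitor")) return(model$params$c - b)
  NULL
}

check_sim_args <- function(dt, t_end, seed) {
  if (!is.numeric(dt) || dt <= 0) stop("'dt' must be > 0")
  if (dt >= 0.1) stop("'dt' >= 0.1 rejected: Euler stability guard")
  if (t_end <= dt) stop("'t_end' must exceed 'dt'")
  if (missing(seed) || is.null(seed) || !is.finite(seed))
    stop("'seed' is mandatory for stochastic simulation (no clock seeding)")
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Euler-Maruyama integration of the Ito Langevin equation
#'
#' Integrates `dx = f(x, b) dt + epsilon * sqrt(B(x, b)) dW` (Ito) with the
#' explicit Euler-Maruyama scheme
#' `x[k+1] = x[k] + f dt + epsilon * sqrt(B dt) * N[k]` and a reflecting
#' boundary at 0 (`x <- |x|`). Two runs with the same seed are
#' bit-identical. Hill-family models run in compiled code; other models use
#' a pure-R loop.
#'
#' @param spec a [build_langevin()] specification.
#' @param b control parameter value.
#' @param x0 initial concentration, `x0 >= 0`.
#' @param t_end final time.
#' @param seed integer seed (mandatory).
#' @param dt time step (`0 < dt < 0.1`).
#' @param thin record every `thin`-th step (the initial state is always
#'   recorded).
#' @param epsilon noise intensity override; `0` gives the deterministic ODE
#'   limit (infinite volume).
#' @param reflect reflect negative excursions at 0 (the boundary handling for
#'   concentration-valued models); disable for custom specs on an unbounded
#'   domain.
#' @return a `trajectory` (fields `times`, `states`, `seed`, `engine`,
#'   `params`).
#' @export
euler_maruyama <- function(spec, b = NA_real_, x0, t_end, seed, dt = 1e-3,
                           thin = 1L, epsilon = NULL, reflect = TRUE) {
  stopifnot(inherits(spec, "langevin_spec"))
  if (reflect && x0 < 0) stop("'x0' must be >= 0 on the reflected domain")
  check_sim_args(dt, t_end, seed)
  eps <- if (is.null(epsilon)) spec$epsilon else epsilon
  nsteps <- round(t_end / dt)
  beff <- if (is.null(spec$model)) NULL else hill_beff(spec$model, b)
  if (!is.null(beff)) {
    a <- spec$model$params$a
    h <- spec$model$params$h
    states <- .cpp_em_hill(a, beff, h, eps, x0, dt, nsteps, as.integer(thin),
                           as.numeric(seed))
  } else {
    states <- with_seed(seed, {
      x <- x0
      nrec <- nsteps %/% thin + 1L
      out <- numeric(nrec)
      out[1L] <- x
      j <- 2L
      sdt <- sqrt(dt)
      for (k in seq_len(nsteps)) {
        Bv <- spec$diffusion_shape(x, b)
        if (Bv < 0) stop("diffusion shape B(x) < 0 encountered at x = ", x)
        x <- x + spec$drift(x, b) * dt + eps * sqrt(Bv) * sdt * rnorm(1L)
        if (reflect && x < 0) x <- -x
        if (k %% thin == 0L) { out[j] <- x; j <- j + 1L }
      }
      out
    })
  }
  times <- seq(0, by = dt * thin, length.out = length(states))
  new_trajectory(times, states, seed, engine = "em",
                 params = list(b = b, x0 = x0, dt = dt, t_end = t_end,
                               thin = thin, epsilon = eps,
                               Omega = spec$Omega))
}

#' Ornstein-Uhlenbeck noise configuration
#'
#' The OU process `dz = -z/tau dt + (epsilon/tau) dW` has correlation time
#' `tau`, stationary variance `epsilon^2 / (2 tau)` and correlation function
#' `var * exp(-|lag|/tau)`; as `tau -> 0` it tends to white noise of
#' intensity `epsilon`.
#'
#' @param tau correlation time (`> 0`).
#' @param epsilon white-noise-limit intensity (`> 0`).
#' @return an object of class `ou_config` with the derived
#'   `stationary_variance`.
#' @export
ou_config <- function(tau, epsilon) {
  stopifnot(tau > 0, epsilon > 0)
  structure(list(tau = tau, epsilon = epsilon,
                 stationary_variance = epsilon^2 / (2 * tau)),
            class = "ou_config")
}

#' Sample path of the Ornstein-Uhlenbeck process
#'
#' Exact discrete-time update
#' `z[k+1] = z[k] exp(-dt/tau) + sd * sqrt(1 - exp(-2 dt/tau)) * N[k]`
#' started from the stationary law.
#'
#' @param ou an [ou_config()].
#' @param t_end final time.
#' @param seed integer seed.
#' @param dt sampling step.
#' @return a `trajectory` with engine `"ou"`.
#' @export
ou_path <- function(ou, t_end, seed, dt = 1e-3) {
  stopifnot(inherits(ou, "ou_config"))
  check_sim_args(dt, t_end, seed)
  nsteps <- round(t_end / dt)
  states <- .cpp_ou_path(ou$tau, ou$epsilon, dt, nsteps, as.numeric(seed))
  new_trajectory(seq(0, by = dt, length.out = length(states)), states,
                 seed, engine = "ou",
                 params = list(tau = ou$tau, epsilon = ou$epsilon, dt = dt,
                               t_end = t_end))
}

#' Colored-noise Langevin integration (Stratonovich-consistent)
#'
#' Integrates the colored-noise counterpart of the white-noise system:
#' `dx = [f(x, b) - (epsilon^2/4) dB/dx] dt + sqrt(B(x, b)) * z(t) dt`,
#' where `z` is an Ornstein-Uhlenbeck process with correlation time `tau`.
#' By the Wong-Zakai theorem the `tau -> 0` limit of a multiplicative OU
#' drive is the Stratonovich interpretation; the drift is therefore written
#' in Stratonovich form (the `-(epsilon^2/4) dB/dx` term is the
#' Ito-to-Stratonovich conversion), so that as `tau -> 0` the process
#' converges to the Ito white-noise system, and the state is advanced with
#' the Heun predictor-corrector scheme (Stratonovich-consistent) while the
#' OU value is held constant within each step and updated exactly between
#' steps. As `tau -> infinity` at fixed intensity the OU variance vanishes
#' and the dynamics approach the deterministic flow of the corrected drift
#' (equivalently, the white-noise system with the noise intensity halved).
#'
#' @inheritParams euler_maruyama
#' @param ou an [ou_config()]; its `epsilon` is the white-noise-limit
#'   intensity.
#' @return a `trajectory` with engine `"colored"`.
#' @export
colored_langevin <- function(spec, b = NA_real_, ou, x0, t_end, seed,
                             dt = 1e-3, thin = 1L) {
  stopifnot(inherits(spec, "langevin_spec"), inherits(ou, "ou_config"),
            x0 >= 0)
  check_sim_args(dt, t_end, seed)
  nsteps <- round(t_end / dt)
  beff <- if (is.null(spec$model)) NULL else hill_beff(spec$model, b)
  if (!is.null(beff)) {
    a <- spec$model$params$a
    h <- spec$model$params$h
    states <- .cpp_heun_ou_hill(a, beff, h, ou$epsilon, ou$tau, x0, dt,
                                nsteps, as.integer(thin), as.numeric(seed))
  } else {
    states <- with_seed(seed, {
      sig <- sqrt(ou$stationary_variance)
      rho <- exp(-dt / ou$tau)
      sres <- sig * sqrt(1 - rho^2)
      z <- sig * rnorm(1L)
      x <- x0
      nrec <- nsteps %/% thin + 1L
      out <- numeric(nrec)
      out[1L] <- x
      j <- 2L
      # Stratonovich-form drift f - (eps^2/4) dB/dx (see the compiled engine)
      Bx <- if (is.null(spec$model)) {
        function(x) {
          hh <- 6e-6 * max(1, abs(x))
          (spec$diffusion_shape(x + hh, b) -
             spec$diffusion_shape(x - hh, b)) / (2 * hh)
        }
      } else {
        function(x) spec_B_deriv(spec$model, x, b, 1L, 0L)
      }
      sdrift <- function(x) spec$drift(x, b) - 0.25 * ou$epsilon^2 * Bx(x)
      for (k in seq_len(nsteps)) {
        d0 <- sdrift(x) + sqrt(spec$diffusion_shape(x, b)) * z
        xp <- abs(x + d0 * dt)
        d1 <- sdrift(xp) + sqrt(spec$diffusion_shape(xp, b)) * z
        x <- x + 0.5 * dt * (d0 + d1)
        if (x < 0) x <- -x
        z <- rho * z + sres * rnorm(1L)
        if (k %% thin == 0L) { out[j] <- x; j <- j + 1L }
      }
      out
    })
  }
  times <- seq(0, by = dt * thin, length.out = length(states))
  new_trajectory(times, states, seed, engine = "colored",
                 params = list(b = b, x0 = x0, dt = dt, t_end = t_end,
                               thin = thin, tau = ou$tau,
                               epsilon = ou$epsilon, Omega = spec$Omega))
}

#' Gillespie simulation of the simple birth-death switch
#'
#' Direct-method stochastic simulation of the one-step process with birth
#' propensity `Omega * g(n / Omega, b)` and death propensity `n`. With
#' `record_dt = NULL` every reaction event is recorded (times strictly
#' increasing); with a positive `record_dt` the held state is sampled on a
#' uniform time grid (equivalent to time-weighted sampling, and bounded
#' memory for long runs).
#'
#' @param model a [regulatory_model()].
#' @param b control parameter value.
#' @param Omega dimensionless cell volume.
#' @param n0 initial molecule count (non-negative integer).
#' @param t_end final time.
#' @param seed integer seed (mandatory).
#' @param record_dt optional uniform recording interval.
#' @return a `trajectory` with engine `"ssa_simple"`; `states` are integer
#'   counts.
#' @export
ssa_simple <- function(model, b, Omega, n0, t_end, seed, record_dt = NULL) {
  stopifnot(inherits(model, "regulatory_model"), Omega > 0,
            n0 >= 0, n0 == round(n0), t_end > 0)
  if (missing(seed) || is.null(seed)) stop("'seed' is mandatory")
  rec <- if (is.null(record_dt)) -1 else record_dt
  beff <- hill_beff(model, b)
  if (!is.null(beff)) {
    res <- .cpp_ssa_hill(model$params$a, beff, model$params$h, Omega,
                         n0, t_end, as.numeric(seed), rec)
  } else {
    res <- with_seed(seed, ssa_generic_r(model, b, Omega, n0, t_end, rec))
  }
  new_trajectory(res$times, res$states, seed, engine = "ssa_simple",
                 params = list(b = b, Omega = Omega, n0 = n0, t_end = t_end,
                               record_dt = record_dt),
                 record = if (rec > 0) "grid" else "events",
                 n_events = res$n_events)
}

# pure-R direct method for models without a compiled fast path (small runs)
ssa_generic_r <- function(model, b, Omega, n0, t_end, rec) {
  n <- n0; t <- 0
  times <- numeric(0); states <- numeric(0)
  if (rec <= 0) { times <- 0; states <- n }
  rec_t <- 0; n_events <- 0
  while (t < t_end) {
    wplus <- Omega * model$g(n / Omega, b)
    a0 <- wplus + n
    t_next <- if (a0 > 0) t + rexp(1L) / a0 else t_end + 1
    if (rec > 0) {
      while (rec_t < t_next && rec_t <= t_end) {
        times <- c(times, rec_t); states <- c(states, n)
        rec_t <- rec_t + rec
      }
    }
    if (t_next > t_end) break
    t <- t_next
    n <- if (runif(1L) * a0 < wplus) n + 1 else n - 1
    n_events <- n_events + 1
    if (rec <= 0) { times <- c(times, t); states <- c(states, n) }
  }
  list(times = times, states = states, n_events = n_events)
}

#' Gillespie simulation of the detailed promoter-binding switch
#'
#' Direct-method simulation of the detailed switch: per promoter copy,
#' production at count rate `a * Omega` (unbound) or `(a + b) * Omega`
#' (bound); cooperative binding of `h` free monomers to an unbound promoter
#' with propensity `(keq * koff / Omega^h) * n (n-1) ... (n-h+1) * d0`
#' (the bound monomers are sequestered); unbinding at rate `koff * d1`
#' releasing the `h` monomers; degradation of free protein at rate `n`.
#' The conservation law `d0 + d1 = dna_copies` holds at every event, and a
#' binding event cannot fire with `n < h` (its propensity is zero).
#'
#' @param p a [detailed_switch_params()].
#' @param t_end final time.
#' @param seed integer seed (mandatory).
#' @param n0 initial free-protein count.
#' @param d1_0 initially bound promoter copies.
#' @param record_dt optional uniform recording interval (default: record
#'   every event).
#' @return a `trajectory` with engine `"ssa_detailed"`; `states` are free
#'   protein counts and `d1` the bound-promoter count.
#' @export
ssa_detailed <- function(p, t_end, seed, n0 = 0, d1_0 = 0L,
                         record_dt = NULL) {
  stopifnot(inherits(p, "detailed_switch_params"), t_end > 0,
            n0 >= 0, n0 == round(n0), d1_0 >= 0, d1_0 <= p$dna_copies)
  if (missing(seed) || is.null(seed)) stop("'seed' is mandatory")
  rec <- if (is.null(record_dt)) -1 else record_dt
  res <- .cpp_ssa_detailed(p$a, p$b, p$h, p$Omega, p$keq, p$koff,
                           p$dna_copies, n0, as.integer(d1_0), t_end,
                           as.numeric(seed), rec)
  new_trajectory(res$times, res$states, seed, engine = "ssa_detailed",
                 params = unclass(p), d1 = res$d1,
                 record = if (rec > 0) "grid" else "events",
                 n_events = res$n_events)
}

#' Equilibrium promoter occupancy with clamped protein level
#'
#' Runs the detailed model's binding/unbinding channels alone, with
#' production and degradation disabled and the free-protein count clamped at
#' `n_clamped`. The time-averaged bound fraction then estimates the two-state
#' equilibrium `keq p^h / (1 + keq p^h)` with `p = n_clamped / Omega`, the
#' quasi-steady-state occupancy.
#'
#' @param p a [detailed_switch_params()].
#' @param n_clamped clamped free-protein count.
#' @param t_end final time.
#' @param seed integer seed.
#' @return list with `occupancy` (time-averaged bound fraction), the
#'   theoretical `qss_occupancy`, and `n_events`.
#' @export
promoter_occupancy_ssa <- function(p, n_clamped, t_end, seed) {
  stopifnot(inherits(p, "detailed_switch_params"))
  res <- .cpp_ssa_binding_only(p$h, p$Omega, p$keq, p$koff, p$dna_copies,
                               n_clamped, t_end, as.numeric(seed))
  x <- n_clamped / p$Omega
  list(occupancy = res$occupancy,
       qss_occupancy = p$keq * x^p$h / (1 + p$keq * x^p$h),
       n_events = res$n_events)
}

#' Export a trajectory as CSV (with JSON parameter sidecar)
#'
#' Writes columns `time`, `state` (and `d1` for the detailed model) plus a
#' `<path>.json` sidecar holding the engine, seed and full parameter record.
#'
#' @param traj a `trajectory`.
#' @param path output CSV path.
#' @param thin optional extra thinning interval (keep every `thin`-th row).
#' @return the CSV path, invisibly.
#' @export
write_trajectory_csv <- function(traj, path, thin = 1L) {
  stopifnot(inherits(traj, "trajectory"))
  idx <- seq(1L, length(traj$times), by = thin)
  df <- data.frame(time = traj$times[idx], state = traj$states[idx])
  if (!is.null(traj$d1)) df$d1 <- traj$d1[idx]
  write.csv(df, path, row.names = FALSE)
  sidecar <- list(engine = traj$engine, seed = traj$seed,
                  record = traj$record, params = traj$params)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
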