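# Shared fixtures and independent oracles, built in code at test time.

# reference auto-activating switch (dimensionless defaults)
REF_MODEL <- hill_activator(a = 0.1, h = 2)
REF_DET <- deterministic_bifurcation_points(REF_MODEL)

# Independent oracle for the h = 2 saddle-nodes: eliminating b from
# f = 0, f_x = 0 by hand gives x^3 - x + 2a = 0 and b = (1 + x^2)^2 / (2x).
# Solved here with polyroot on the cubic -- a different path from the
# package's 2-D Newton on (f, f_x).
hill2_saddle_oracle <- function(a) {
  z <- polyroot(c(2 * a, -1, 0, 1))
  x <- sort(Re(z)[abs(Im(z)) < 1e-9 & Re(z) > 0])
  b <- (1 + x^2)^2 / (2 * x)
  o <- order(b)
  list(x = x[o], b = b[o])  # ascending in b: (lower, upper)
}

# Kolmogorov-Smirnov distance between samples and an analytic density on a
# uniform grid.
ks_to_density <- function(samples, dens) {
  dx <- dens$grid[2] - dens$grid[1]
  cdf <- cumsum(dens$density) * dx
  cdf <- cdf / max(cdf)
  max(abs(stats::ecdf(samples)(dens$grid) - cdf))
}

# total-variation distance between an empirical count histogram and an exact
# discrete distribution
tv_to_distribution <- function(counts, dist) {
  n_max <- max(counts, dist$n)
  emp <- tabulate(counts + 1L, nbins = n_max + 1L) / length(counts)
  exa <- c(dist$probs, rep(0, n_max + 1L - length(dist$probs)))[1:(n_max + 1L)]
  0.5 * sum(abs(emp - exa))
}

# wrap a plain sample vector as a grid-recorded trajectory
make_grid_traj <- function(states, dt = 1e-3, b = NA_real_) {
  structure(list(times = seq(0, by = dt, length.out = length(states)),
                 states = states, seed = 0L, engine = "em",
                 params = list(b = b, dt = dt), record = "grid"),
            class = "trajectory")
}

# two-state telegraph signal with exponential dwell times and additive
# observation noise; levels 0.2 (low) and 1.8 (high)
telegraph_traj <- function(mu_low, mu_high, t_end, dt, seed,
                           noise_sd = 0.05) {
  set.seed(seed)
  t <- 0; state <- 1L
  ts <- numeric(0); ss <- integer(0)
  while (t < t_end) {
    ts <- c(ts, t); ss <- c(ss, state)
    t <- t + rexp(1L, 1 / if (state == 1L) mu_high else mu_low)
    state <- 1L - state
  }
  tt <- seq(0, t_end, by = dt)
  lvl <- ss[findInterval(tt, ts)]
  make_grid_traj(ifelse(lvl == 1L, 1.8, 0.2) +
                   rnorm(length(tt), 0, noise_sd), dt = dt)
}

# low-state occupancy of a trajectory, using the analytic hysteresis band
low_state_occupancy <- function(traj, spec, b, scale = 1) {
  ex <- density_extrema(spec, b)
  if (length(ex$maxima) < 2 || !length(ex$minima)) {
    # unimodal analytic density: count time below the deterministic unstable
    # branch (low state cannot be committed; fall back to a fixed cut)
    thr <- 0.45 * scale
    return(mean(traj$states[-seq_len(length(traj$states) %/% 10)] < thr))
  }
  thr <- hysteresis_band(ex) * scale
  dw <- dwell_times(traj, thr[1], thr[2], burnin_fraction = 0.1)
  unname(dw$occupancy["low"])
}
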