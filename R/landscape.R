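## Landscape pipeline: empirical stationary densities, Gaussian peak
## detection, mono/bistable classification, stochastic bifurcation diagrams,
## and dwell-time statistics.

#' Empirical stationary density of a trajectory
#'
#' Histogram density of the post-burn-in samples. Event-recorded SSA
#' trajectories are weighted by the holding time of each state; fixed-step
#' (or grid-recorded) trajectories are weighted uniformly. The burn-in
#' removes the leading fraction of samples: with `burnin_fraction = 0.1` on a
#' 1000-sample trajectory exactly the last 900 samples are used.
#'
#' @param traj a `trajectory`.
#' @param bins number of histogram bins.
#' @param burnin_fraction fraction of samples discarded from the start.
#' @param scale multiplies the states before binning (e.g. `1/Omega` to
#'   convert counts to concentration).
#' @param range optional binning range (length 2); defaults to the sample
#'   range padded by half a bin.
#' @return a `stationary_density` with `quadrature = "midpoint"` (the
#'   integral is the sum of `density * widths`, exactly 1).
#' @export
empirical_density <- function(traj, bins = 200L, burnin_fraction = 0.1,
                              scale = 1, range = NULL) {
  stopifnot(inherits(traj, "trajectory"),
            burnin_fraction >= 0, burnin_fraction < 1)
  n <- length(traj$states)
  start <- floor(burnin_fraction * n) + 1L
  if (start > n) stop("burn-in removes every sample")
  s <- traj$states[start:n] * scale
  if (identical(traj$record, "events")) {
    tt <- traj$times[start:n]
    w <- diff(tt)
    if (!length(w) || sum(w) <= 0) stop("empty post-burn-in sample")
    s <- s[-length(s)]  # each state is held until the next event
  } else {
    w <- rep(1, length(s))
  }
  if (is.null(range)) {
    pad <- diff(base::range(s)) / (2 * bins)
    if (pad == 0) pad <- max(abs(s[1]), 1) * 1e-3
    range <- base::range(s) + c(-pad, pad)
  }
  breaks <- seq(range[1], range[2], length.out = bins + 1L)
  idx <- findInterval(s, breaks, rightmost.closed = TRUE)
  inside <- idx >= 1L & idx <= bins
  wsum <- vapply(seq_len(bins), function(i) sum(w[inside & idx == i]),
                 numeric(1))
  width <- diff(breaks)
  dens <- wsum / (sum(w[inside]) * width)
  structure(list(grid = (breaks[-1L] + breaks[-(bins + 1L)]) / 2,
                 density = dens,
                 log_density = ifelse(dens > 0, log(dens), -Inf),
                 widths = width, quadrature = "midpoint",
                 n_samples = length(s), b = traj$params$b,
                 epsilon = traj$params$epsilon),
            class = "stationary_density")
}

#' Gaussian peak detection on a stationary density
#'
#' Smooths the density with a Gaussian kernel, scans for local maxima above a
#' relative prominence threshold, and refines each candidate by a local
#' Gaussian least-squares fit (quadratic fit to the log-density over +/- 2
#' bandwidths), returning refined centers, heights and widths. Candidates
#' whose integrated mass over +/- 2 bandwidths falls below `min_mass` are
#' dropped: the detection threshold materially determines where a simulated
#' branch of the bifurcation diagram ends, so it is a first-class, reported
#' setting.
#'
#' @param density a `stationary_density` (analytic or empirical) on a uniform
#'   grid.
#' @param bandwidth kernel bandwidth; default is Silverman's rule on the
#'   density treated as a weighted sample, floored at 2 grid steps.
#' @param prominence minimum peak height relative to the global maximum of
#'   the smoothed density.
#' @param min_mass minimum integrated probability mass of a reported peak.
#' @return an object of class `peak_set`: a data.frame with columns
#'   `location`, `height`, `width` (sorted by location), with the detection
#'   configuration in attributes.
#' @export
gaussian_peak_detect <- function(density, bandwidth = NULL,
                                 prominence = 1e-3, min_mass = 1e-4) {
  stopifnot(inherits(density, "stationary_density"))
  x <- density$grid
  p <- density$density
  dx <- x[2] - x[1]
  if (is.null(bandwidth)) {
    w <- p / sum(p)
    mu <- sum(w * x)
    sdv <- sqrt(max(sum(w * (x - mu)^2), dx^2))
    n_eff <- if (!is.null(density$n_samples)) density$n_samples else length(x)
    bandwidth <- max(0.9 * sdv * n_eff^(-1/5), 2 * dx)
  }
  # Gaussian kernel smoothing with edge renormalization
  half <- max(1L, ceiling(4 * bandwidth / dx))
  kern <- exp(-0.5 * ((-half:half) * dx / bandwidth)^2)
  sm <- as.numeric(stats::filter(c(rep(0, half), p, rep(0, half)),
                                 kern / sum(kern), sides = 2))
  norm <- as.numeric(stats::filter(c(rep(0, half), rep(1, length(p)),
                                     rep(0, half)),
                                   kern / sum(kern), sides = 2))
  sm <- (sm / norm)[(half + 1L):(half + length(p))]
  # local maxima (boundaries included)
  k <- length(sm)
  is_max <- c(sm[1] > sm[2], sm[2:(k - 1)] >= sm[1:(k - 2)] &
                sm[2:(k - 1)] > sm[3:k], sm[k] > sm[k - 1])
  cand <- which(is_max & sm >= prominence * max(sm))
  peaks <- data.frame(location = numeric(0), height = numeric(0),
                      width = numeric(0))
  for (i in cand) {
    win <- which(abs(x - x[i]) <= 2 * bandwidth & sm > 0)
    mass <- sum(p[win]) * dx
    if (mass < min_mass) next
    loc <- x[i]; hgt <- sm[i]; wid <- bandwidth
    if (length(win) >= 5) {
      fit <- lm(log(sm[win]) ~ poly(x[win], 2, raw = TRUE))
      cf <- coef(fit)
      if (is.finite(cf[3]) && cf[3] < 0) {
        ctr <- -cf[2] / (2 * cf[3])
        if (ctr >= min(x[win]) && ctr <= max(x[win])) {
          loc <- ctr
          wid <- sqrt(-1 / (2 * cf[3]))
          hgt <- exp(cf[1] + cf[2] * ctr + cf[3] * ctr^2)
        }
      }
    }
    peaks <- rbind(peaks,
                   data.frame(location = loc, height = hgt, width = wid))
  }
  # merge refined candidates that collapsed onto the same peak
  if (nrow(peaks) > 1) {
    peaks <- peaks[order(peaks$location), , drop = FALSE]
    keep <- c(TRUE, diff(peaks$location) > bandwidth / 2)
    peaks <- peaks[keep, , drop = FALSE]
  }
  rownames(peaks) <- NULL
  structure(peaks, class = c("peak_set", "data.frame"),
            detection_cfg = list(bandwidth = bandwidth,
                                 prominence = prominence,
                                 min_mass = min_mass))
}

#' Dwell-time statistics by hysteretic thresholding
#'
#' Assigns each sample to the low or high phenotypic state with a hysteresis
#' band: the trajectory enters the high state only above `high` and the low
#' state only below `low`, so rapid noise crossings inside the band are not
#' counted as switches. Returns completed dwell times per state, their means,
#' and the time-occupancy fractions.
#'
#' @param traj a `trajectory`.
#' @param low lower threshold (enter the low state below it).
#' @param high upper threshold (enter the high state above it), `high > low`.
#' @param burnin_fraction fraction of samples discarded from the start.
#' @return list of class `dwell_stats`: `low` and `high` each with `dwells`
#'   (completed dwell-time samples), `mean`, `n`; plus `occupancy` (fractions
#'   of assigned time) and `n_switches`.
#' @export
dwell_times <- function(traj, low, high, burnin_fraction = 0) {
  stopifnot(inherits(traj, "trajectory"), low < high)
  n <- length(traj$states)
  start <- floor(burnin_fraction * n) + 1L
  s <- traj$states[start:n]
  tt <- traj$times[start:n]
  lab <- ifelse(s > high, 1L, ifelse(s < low, -1L, 0L))
  # carry the last committed state forward through the hysteresis band
  idx <- cumsum(lab != 0L)
  committed <- c(NA_integer_, lab[lab != 0L])[idx + 1L]
  valid <- !is.na(committed)
  if (!any(valid))
    return(structure(list(low = list(dwells = numeric(0), mean = NA_real_,
                                     n = 0L),
                          high = list(dwells = numeric(0), mean = NA_real_,
                                      n = 0L),
                          occupancy = c(low = NA_real_, high = NA_real_),
                          n_switches = 0L),
                     class = "dwell_stats"))
  st <- committed[valid]
  tv <- tt[valid]
  change <- which(diff(st) != 0L)
  seg_start <- c(1L, change + 1L)
  seg_state <- st[seg_start]
  seg_t0 <- tv[seg_start]
  seg_t1 <- c(tv[change + 1L], tv[length(tv)])
  dur <- seg_t1 - seg_t0
  k <- length(dur)
  completed <- if (k > 2L) 2:(k - 1L) else integer(0)  # interior dwells only
  dl <- dur[completed][seg_state[completed] == -1L]
  dh <- dur[completed][seg_state[completed] == 1L]
  occ_l <- sum(dur[seg_state == -1L]) / sum(dur)
  structure(list(
    low = list(dwells = dl, mean = if (length(dl)) mean(dl) else NA_real_,
               n = length(dl)),
    high = list(dwells = dh, mean = if (length(dh)) mean(dh) else NA_real_,
                n = length(dh)),
    occupancy = c(low = occ_l, high = 1 - occ_l),
    n_switches = length(change)),
    class = "dwell_stats")
}

#' @export
print.dwell_stats <- function(x, ...) {
  cat("<dwell_stats>", x$n_switches, "switches\n")
  cat(sprintf("  low : n = %d, mean dwell = %s, occupancy = %.4f\n",
              x$low$n, format(x$low$mean, digits = 5), x$occupancy["low"]))
  cat(sprintf("  high: n = %d, mean dwell = %s, occupancy = %.4f\n",
              x$high$n, format(x$high$mean, digits = 5), x$occupancy["high"]))
  invisible(x)
}

#' Hysteresis band around the unstable extremum of a bimodal density
#'
#' Places the dwell-time thresholds 25% of the way from the unstable
#' extremum toward each adjacent density mode (asymmetric, so neither
#' threshold can cross a mode or fall below zero however far apart the modes
#' are).
#'
#' @param ex an [density_extrema()] result with two maxima and one minimum.
#' @param frac fraction of the distance to each mode.
#' @return `c(low, high)` thresholds.
#' @export
hysteresis_band <- function(ex, frac = 0.25) {
  stopifnot(inherits(ex, "extrema_set"))
  if (length(ex$maxima) < 2 || !length(ex$minima))
    stop("density is not bimodal: cannot place a hysteresis band")
  xu <- ex$minima[1]
  lo_mode <- max(ex$maxima[ex$maxima < xu])
  hi_mode <- min(ex$maxima[ex$maxima > xu])
  c(xu - frac * (xu - lo_mode), xu + frac * (hi_mode - xu))
}

#' Stochastic bifurcation diagram sweep
#'
#' Sweeps the control parameter and records, per method, the branch positions
#' and the modality class: `"deterministic"` uses the fixed points (stable
#' where `df/dx < 0`), `"langevin"` the extrema of the analytic stationary
#' density, `"exact"` the modes of the birth-death stationary law (reported
#' as `x = n / Omega`), and `"simulation"` the Gaussian-detected peaks of an
#' empirical density (Euler-Maruyama or SSA engine). The system counts as
#' bistable at a given `b` when it has two stable records there; the per-
#' method bistable interval is the `b`-range with two stable records.
#'
#' @param model a [regulatory_model()].
#' @param b_grid control parameter values to sweep.
#' @param Omega cell volume (sets the noise intensity for all stochastic
#'   methods).
#' @param methods subset of `c("deterministic", "langevin", "exact",
#'   "simulation")`.
#' @param engine simulation engine for the `"simulation"` method: `"em"`
#'   (Langevin) or `"ssa"` (exact jump process).
#' @param seed base seed for simulation sweeps (incremented per `b`).
#' @param t_end,dt,bins,burnin_fraction simulation/histogram settings.
#' @param peak_cfg list of [gaussian_peak_detect()] settings
#'   (`bandwidth`, `prominence`, `min_mass`).
#' @param detailed optional [detailed_switch_params()]; when supplied the
#'   `"simulation"` method runs the detailed promoter-binding model (its `b`
#'   field is replaced by each grid value).
#' @return an object of class `bifurcation_diagram`: list with `records` (a
#'   tidy data.frame `method, b, x, type`), `intervals` (named list of
#'   per-method bistable `b`-intervals, `NULL` when never bistable),
#'   `failures`, and the settings.
#' @export
diagram_sweep <- function(model, b_grid, Omega,
                          methods = c("deterministic", "langevin", "exact"),
                          engine = c("em", "ssa"), seed = 1L,
                          t_end = 2e4, dt = 1e-3, bins = 150L,
                          burnin_fraction = 0.1, peak_cfg = list(),
                          detailed = NULL) {
  stopifnot(inherits(model, "regulatory_model"))
  engine <- match.arg(engine)
  methods <- match.arg(methods, c("deterministic", "langevin", "exact",
                                  "simulation"), several.ok = TRUE)
  spec <- build_langevin(model, Omega)
  recs <- list()
  failures <- list()
  add <- function(method, b, x, type) {
    recs[[length(recs) + 1L]] <<- data.frame(method = method, b = b,
                                             x = x, type = type)
  }
  for (i in seq_along(b_grid)) {
    b <- b_grid[i]
    for (method in methods) {
      res <- tryCatch({
        if (method == "deterministic") {
          fp <- deterministic_fixed_points(b, model)
          fx <- vapply(fp, function(r) spec_f_deriv(model, r, b, 1L, 0L),
                       numeric(1))
          add(method, b, fp, ifelse(fx < 0, "stable", "unstable"))
        } else if (method == "langevin") {
          ex <- density_extrema(spec, b)
          if (length(ex$maxima)) add(method, b, ex$maxima, "stable")
          if (length(ex$minima)) add(method, b, ex$minima, "unstable")
        } else if (method == "exact") {
          dd <- birth_death_stationary(model, b, Omega)
          md <- discrete_modes(dd)
          add(method, b, md / Omega, "stable")
        } else {
          traj <- if (!is.null(detailed)) {
            p <- detailed; p$b <- b; p$Omega <- Omega
            x_init <- max(deterministic_fixed_points(b, model))
            ssa_detailed(p, t_end = t_end, seed = seed + i,
                         n0 = round(x_init * Omega),
                         record_dt = max(dt * 10, 0.05))
          } else if (engine == "ssa") {
            x_init <- max(deterministic_fixed_points(b, model))
            ssa_simple(model, b, Omega, n0 = round(x_init * Omega),
                       t_end = t_end, seed = seed + i,
                       record_dt = max(dt * 10, 0.05))
          } else {
            x_init <- max(deterministic_fixed_points(b, model))
            euler_maruyama(spec, b, x0 = x_init, t_end = t_end,
                           seed = seed + i, dt = dt, thin = 10L)
          }
          scl <- if (traj$engine %in% c("ssa_simple", "ssa_detailed"))
            1 / Omega else 1
          dens <- empirical_density(traj, bins = bins,
                                    burnin_fraction = burnin_fraction,
                                    scale = scl)
          pk <- do.call(gaussian_peak_detect, c(list(dens), peak_cfg))
          if (nrow(pk)) add(method, b, pk$location, "stable")
        }
        NULL
      }, error = function(e) conditionMessage(e))
      if (!is.null(res))
        failures[[length(failures) + 1L]] <- list(method = method, b = b,
                                                  message = res)
    }
  }
  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(method = character(0), b = numeric(0), x = numeric(0),
               type = character(0))
  intervals <- lapply(setNames(methods, methods), function(m) {
    sub <- records[records$method == m & records$type == "stable", ]
    nb <- vapply(split(sub$x, sub$b), length, integer(1))
    bb <- as.numeric(names(nb))[nb >= 2L]
    if (length(bb)) range(bb) else NULL
  })
  structure(list(records = records, intervals = intervals,
                 failures = failures,
                 settings = list(Omega = Omega, engine = engine, seed = seed,
                                 t_end = t_end, dt = dt, bins = bins,
                                 burnin_fraction = burnin_fraction,
                                 peak_cfg = peak_cfg,
                                 detailed = !is.null(detailed))),
            class = "bifurcation_diagram")
}

#' @export
print.bifurcation_diagram <- function(x, ...) {
  cat("<bifurcation_diagram>", nrow(x$records), "records, Omega =",
      x$settings$Omega, "\n")
  for (m in names(x$intervals)) {
    iv <- x$intervals[[m]]
    cat(sprintf("  %-13s bistable b-interval: %s\n", m,
                if (is.null(iv)) "none detected" else
                  paste(format(iv, digits = 6), collapse = " .. ")))
  }
  if (length(x$failures)) cat("  failures:", length(x$failures), "\n")
  invisible(x)
}

#' Export a bifurcation diagram
#'
#' Writes the tidy records CSV (`method, b, x, type`) and a JSON summary of
#' the per-method bistable intervals.
#'
#' @param diag a `bifurcation_diagram`.
#' @param csv_path records CSV path.
#' @param json_path optional intervals JSON path.
#' @return `csv_path`, invisibly.
#' @export
write_diagram_csv <- function(diag, csv_path, json_path = NULL) {
  stopifnot(inherits(diag, "bifurcation_diagram"))
  write.csv(diag$records, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(diag$intervals, json_path, auto_unbox = TRUE,
                         digits = NA)
  invisible(csv_path)
}
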