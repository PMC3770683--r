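## Run configuration: flat key=value config files, CLI overrides, validated
## defaults, and the run_* commands behind the command-line interface.

run_config_defaults <- function() {
  list(
    # model
    a = 0.1, b = 2.2, h = 2, omega = 50,
    keq = 1, koff = 100, dna_copies = 1, tau = 0.01,
    # engine
    dt = 1e-3, t_end = 1e4, burnin = 0.1, bins = 150, seed = 1,
    thin = 10, x0 = NA_real_, record_dt = NA_real_, engine = "em",
    order = 2,
    # sweep
    b_min = 1.2, b_max = 3.4, b_steps = 23,
    methods = c("deterministic", "langevin", "exact"),
    # output
    out_dir = "stochbif-out"
  )
}

.numeric_keys <- c("a", "b", "h", "omega", "keq", "koff", "dna_copies",
                   "tau", "dt", "t_end", "burnin", "bins", "seed", "thin",
                   "x0", "record_dt", "order", "b_min", "b_max", "b_steps")

#' Load and validate a run configuration
#'
#' Reads a flat `key = value` config file (lines `key = value` or
#' `key: value`, `#` comments allowed), applies overrides on top, and
#' validates every field against the owning module's constraints (parameter
#' records are constructed once as a check). Unknown keys are rejected.
#'
#' @param path optional config file path.
#' @param overrides named list (e.g. from CLI flags) applied after the file.
#' @return a validated list of class `run_config`.
#' @export
load_run_config <- function(path = NULL, overrides = list()) {
  cfg <- run_config_defaults()
  from_file <- if (!is.null(path)) parse_flat_config(path) else list()
  for (src in list(from_file, overrides)) {
    if (!length(src)) next
    unknown <- setdiff(names(src), names(cfg))
    if (length(unknown))
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
    cfg <- modifyList(cfg, src)
  }
  for (k in .numeric_keys) cfg[[k]] <- as.numeric(cfg[[k]])
  if (is.character(cfg$methods) && length(cfg$methods) == 1L)
    cfg$methods <- strsplit(cfg$methods, ",")[[1L]]
  cfg$methods <- match.arg(trimws(cfg$methods),
                           c("deterministic", "langevin", "exact",
                             "simulation"), several.ok = TRUE)
  cfg$engine <- match.arg(cfg$engine, c("em", "colored", "ssa-simple",
                                        "ssa-detailed"))
  # revalidate via the owning constructors
  hill_switch_params(cfg$a, cfg$b, cfg$h, cfg$omega)
  detailed_switch_params(cfg$a, cfg$b, cfg$h, cfg$omega, cfg$keq, cfg$koff,
                         cfg$dna_copies)
  if (cfg$tau <= 0) stop("'tau' must be > 0")
  if (cfg$b_min >= cfg$b_max) stop("'b_min' must be below 'b_max'")
  if (cfg$seed != round(cfg$seed)) stop("'seed' must be an integer")
  structure(cfg, class = "run_config")
}

parse_flat_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*[=:]\\s*(.*)$",
                                ln))[[1L]]
    if (length(m) != 3L)
      stop("cannot parse config line: '", ln, "' (expected key = value)")
    val <- trimws(m[3L])
    num <- suppressWarnings(as.numeric(val))
    out[[m[2L]]] <- if (!is.na(num)) num else val
  }
  out
}

run_manifest <- function(cfg, out_dir, artifacts) {
  manifest <- list(
    package = "stochbif",
    version = as.character(utils::packageVersion("stochbif")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(cfg),
    artifacts = artifacts
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  path
}

cfg_model <- function(cfg) hill_activator(a = cfg$a, h = cfg$h)

#' Locate bifurcation points (deterministic, perturbative, continuation)
#'
#' Computes, for both branches, the deterministic saddle-node, the order-1
#' and order-2 perturbative predictions at the configured noise intensity,
#' and the continuation solution, and writes them as JSON records plus a run
#' manifest.
#'
#' @param cfg a [load_run_config()] result.
#' @return invisibly, the list of [bifurcation_point()]s.
#' @export
run_bifurcate <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  model <- cfg_model(cfg)
  spec <- build_langevin(model, cfg$omega)
  det <- deterministic_bifurcation_points(model)
  if (!det$bistable) stop("no bistable region for these parameters")
  pts <- list(det$lower, det$upper)
  for (br in c("lower", "upper")) {
    for (ord in 1:2)
      pts[[length(pts) + 1L]] <-
        predict_shift(shift_series(model, br, order = ord), spec$epsilon)
    pts[[length(pts) + 1L]] <- stochastic_bifurcation_solve(spec, br)
  }
  path <- file.path(cfg$out_dir, "bifurcation_points.json")
  write_bifurcation_json(pts, path)
  run_manifest(cfg, cfg$out_dir, list(bifurcation_points = path))
  invisible(pts)
}

#' Analytic and exact stationary distributions at one parameter point
#'
#' Writes the Langevin stationary density (CSV), its extrema (CSV), the exact
#' birth-death distribution (CSV) and its modes (JSON), plus a manifest.
#'
#' @param cfg a [load_run_config()] result.
#' @return invisibly, a list with the density, extrema and distribution.
#' @export
run_density <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  model <- cfg_model(cfg)
  spec <- build_langevin(model, cfg$omega)
  dens <- stationary_density(spec, cfg$b)
  ex <- density_extrema(spec, cfg$b)
  dd <- birth_death_stationary(model, cfg$b, cfg$omega)
  p1 <- write_density_csv(dens, file.path(cfg$out_dir, "density.csv"))
  exdf <- data.frame(
    b = cfg$b,
    x = c(ex$maxima, ex$minima),
    type = c(rep("max", length(ex$maxima)), rep("min", length(ex$minima))))
  p2 <- file.path(cfg$out_dir, "extrema.csv")
  write.csv(exdf, p2, row.names = FALSE)
  p3 <- write_distribution_csv(dd, file.path(cfg$out_dir,
                                             "exact_distribution.csv"))
  p4 <- file.path(cfg$out_dir, "exact_modes.json")
  jsonlite::write_json(list(Omega = cfg$omega, b = cfg$b,
                            modes_n = discrete_modes(dd),
                            modes_x = discrete_modes(dd) / cfg$omega),
                       p4, auto_unbox = TRUE, digits = NA)
  run_manifest(cfg, cfg$out_dir,
               list(density = p1, extrema = p2, exact_distribution = p3,
                    exact_modes = p4))
  invisible(list(density = dens, extrema = ex, distribution = dd))
}

#' Simulate one trajectory with the configured engine
#'
#' Engines: `"em"` (Euler-Maruyama), `"colored"` (OU-driven Heun),
#' `"ssa-simple"`, `"ssa-detailed"`. Writes the trajectory CSV with JSON
#' sidecar and a manifest.
#'
#' @param cfg a [load_run_config()] result.
#' @return invisibly, the `trajectory`.
#' @export
run_simulate <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  model <- cfg_model(cfg)
  spec <- build_langevin(model, cfg$omega)
  x0 <- if (is.na(cfg$x0)) max(deterministic_fixed_points(cfg$b, model))
        else cfg$x0
  rec <- if (is.na(cfg$record_dt)) NULL else cfg$record_dt
  traj <- switch(cfg$engine,
    "em" = euler_maruyama(spec, cfg$b, x0 = x0, t_end = cfg$t_end,
                          seed = cfg$seed, dt = cfg$dt, thin = cfg$thin),
    "colored" = colored_langevin(spec, cfg$b,
                                 ou_config(cfg$tau, spec$epsilon),
                                 x0 = x0, t_end = cfg$t_end, seed = cfg$seed,
                                 dt = cfg$dt, thin = cfg$thin),
    "ssa-simple" = ssa_simple(model, cfg$b, cfg$omega,
                              n0 = round(x0 * cfg$omega),
                              t_end = cfg$t_end, seed = cfg$seed,
                              record_dt = rec),
    "ssa-detailed" = {
      p <- detailed_switch_params(cfg$a, cfg$b, cfg$h, cfg$omega, cfg$keq,
                                  cfg$koff, cfg$dna_copies)
      ssa_detailed(p, t_end = cfg$t_end, seed = cfg$seed,
                   n0 = round(x0 * cfg$omega), record_dt = rec)
    })
  path <- file.path(cfg$out_dir, "trajectory.csv")
  write_trajectory_csv(traj, path)
  run_manifest(cfg, cfg$out_dir, list(trajectory = path))
  invisible(traj)
}

#' Bifurcation-diagram sweep over the control parameter
#'
#' Runs [diagram_sweep()] with the configured methods over
#' `seq(b_min, b_max, length.out = b_steps)` and writes the tidy records CSV,
#' the per-method bistable intervals JSON, and a manifest.
#'
#' @param cfg a [load_run_config()] result.
#' @return invisibly, the `bifurcation_diagram`.
#' @export
run_diagram <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  model <- cfg_model(cfg)
  b_grid <- seq(cfg$b_min, cfg$b_max, length.out = cfg$b_steps)
  detailed <- if (identical(cfg$engine, "ssa-detailed"))
    detailed_switch_params(cfg$a, cfg$b, cfg$h, cfg$omega, cfg$keq,
                           cfg$koff, cfg$dna_copies) else NULL
  diag <- diagram_sweep(model, b_grid, cfg$omega, methods = cfg$methods,
                        engine = if (identical(cfg$engine, "ssa-simple"))
                          "ssa" else "em",
                        seed = cfg$seed, t_end = cfg$t_end, dt = cfg$dt,
                        bins = cfg$bins, burnin_fraction = cfg$burnin,
                        detailed = detailed)
  p1 <- file.path(cfg$out_dir, "diagram.csv")
  p2 <- file.path(cfg$out_dir, "bistable_intervals.json")
  write_diagram_csv(diag, p1, p2)
  run_manifest(cfg, cfg$out_dir, list(diagram = p1, intervals = p2))
  invisible(diag)
}

#' Dwell-time statistics of a simulated trajectory
#'
#' Simulates with the configured engine and places the hysteresis band
#' asymmetrically around the analytic unstable extremum: each threshold sits
#' 25% of the way from the unstable extremum toward the adjacent density
#' mode (a symmetric fraction of the full inter-mode distance can cross zero
#' when the modes are far apart). Writes the dwell statistics as JSON plus a
#' manifest.
#'
#' @param cfg a [load_run_config()] result.
#' @return invisibly, the `dwell_stats`.
#' @export
run_dwell <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  model <- cfg_model(cfg)
  spec <- build_langevin(model, cfg$omega)
  traj <- run_simulate(cfg)
  ex <- density_extrema(spec, cfg$b)
  if (length(ex$maxima) < 2 || !length(ex$minima))
    stop("analytic density is unimodal at b = ", cfg$b,
         ": no hysteresis band can be placed")
  thr <- hysteresis_band(ex)
  scl <- if (traj$engine %in% c("ssa_simple", "ssa_detailed")) cfg$omega else 1
  dw <- dwell_times(traj, low = thr[1] * scl, high = thr[2] * scl,
                    burnin_fraction = cfg$burnin)
  path <- file.path(cfg$out_dir, "dwell.json")
  jsonlite::write_json(list(low = dw$low, high = dw$high,
                            occupancy = as.list(dw$occupancy),
                            n_switches = dw$n_switches),
                       path, auto_unbox = TRUE, digits = NA)
  run_manifest(cfg, cfg$out_dir, list(dwell = path))
  invisible(dw)
}

#' Command-line entry point
#'
#' Thin dispatcher behind the `inst/cli/stochbif.R` script. Subcommands:
#' `bifurcate`, `density`, `simulate`, `diagram`, `dwell`. Flags are
#' `--key value` pairs matching the configuration keys; `--config FILE`
#' loads a flat key=value file first, then flags override it. Stochastic
#' subcommands require `--seed`.
#'
#' @param argv character vector of arguments (subcommand first).
#' @return exit status (0 on success), invisibly.
#' @export
run_command <- function(argv) {
  usage <- paste0(
    "usage: stochbif <bifurcate|density|simulate|diagram|dwell> ",
    "[--config FILE] [--key value ...]")
  if (!length(argv)) { message(usage); return(invisible(1L)) }
  sub <- argv[1L]
  if (!sub %in% c("bifurcate", "density", "simulate", "diagram", "dwell")) {
    message("unknown subcommand '", sub, "'\n", usage)
    return(invisible(1L))
  }
  flags <- argv[-1L]
  if (length(flags) %% 2L != 0L) {
    message("flags must come in --key value pairs\n", usage)
    return(invisible(1L))
  }
  keys <- flags[c(TRUE, FALSE)]
  vals <- flags[c(FALSE, TRUE)]
  if (length(keys) && !all(startsWith(keys, "--"))) {
    message("flags must start with '--'\n", usage)
    return(invisible(1L))
  }
  keys <- sub("^--", "", keys)
  cfg_path <- NULL
  if ("config" %in% keys) {
    cfg_path <- vals[keys == "config"][1L]
    vals <- vals[keys != "config"]; keys <- keys[keys != "config"]
  }
  overrides <- as.list(vals)
  names(overrides) <- keys
  num <- names(overrides) %in% .numeric_keys
  overrides[num] <- lapply(overrides[num], as.numeric)
  status <- tryCatch({
    cfg <- load_run_config(cfg_path, overrides)
    seed_given <- "seed" %in% keys ||
      (!is.null(cfg_path) && "seed" %in% names(parse_flat_config(cfg_path)))
    if (sub %in% c("simulate", "diagram", "dwell") && !seed_given)
      stop("--seed is mandatory for stochastic subcommands")
    switch(sub,
           bifurcate = run_bifurcate(cfg),
           density = run_density(cfg),
           simulate = run_simulate(cfg),
           diagram = run_diagram(cfg),
           dwell = run_dwell(cfg))
    message("wrote artifacts to ", cfg$out_dir)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
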