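# one manifest per run, written alongside the outputs
write_manifest <- function(outdir, command, config, seeds, outputs) {
  manifest <- list(
    command = command,
    config = config,
    seeds = seeds,
    outputs = outputs,
    package_version = as.character(utils::packageVersion("qstox")),
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA, null = "null")
  path
}

#' Simulate the myelosuppression model and write a report
#'
#' Runs [simulate_friberg()] for one parameter set and schedule, writing a
#' trajectory CSV (with CTCAE grades), a recovery summary JSON, and a run
#' manifest. For repeated schedules the summary also records the pre-dose
#' circulating count of each cycle and whether the count returns to within
#' the tolerance band of baseline between consecutive doses.
#'
#' @param params A [friberg_params()] object or a config file path.
#' @param schedule A [treatment_schedule()] or a schedule JSON path.
#' @param outdir Output directory (created if needed).
#' @param horizon Simulation horizon, hours.
#' @param dt_out Output grid step, hours.
#' @param tolerance_fraction Recovery band half-width.
#' @return List with the summary and the output paths, invisibly.
#' @export
run_hematology_report <- function(params, schedule, outdir, horizon = 2160,
                                  dt_out = 1, tolerance_fraction = 0.02) {
  if (is.character(params)) params <- read_model_config(params)
  if (is.character(schedule)) schedule <- read_schedule(schedule)
  stopifnot(inherits(params, "friberg_params"),
            inherits(schedule, "treatment_schedule"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  traj <- simulate_friberg(params, schedule, horizon = horizon, dt_out = dt_out)
  traj_path <- file.path(outdir, "trajectory.csv")
  write_trajectory(traj, traj_path, grades = TRUE)

  summ <- recovery_summary(traj, tolerance_fraction)
  ev <- schedule[schedule$kill_fraction > 0, , drop = FALSE]
  if (nrow(ev) >= 2L) {
    pre_dose <- vapply(ev$time_h[-1L], function(t) {
      i <- max(which(traj$times < t))
      traj$states[i, "circ"]
    }, numeric(1))
    summ$pre_dose_circ <- pre_dose
    # a cycle "returns to homeostatic values" if its pre-dose count is near
    # baseline; large feedback-driven oscillations push it far away
    summ$returns_to_baseline_between_doses <-
      all(abs(pre_dose - params$circ0) <= 0.25 * params$circ0)
  }
  summ_path <- file.path(outdir, "recovery.json")
  jsonlite::write_json(summ, summ_path, auto_unbox = TRUE, digits = NA, null = "null")
  man <- write_manifest(outdir, "simulate-hematology",
                        config = c(params[c("circ0", "mtt", "gamma", "n_transit")],
                                   list(horizon_h = horizon, dt_out_h = dt_out,
                                        tolerance_fraction = tolerance_fraction)),
                        seeds = integer(0),
                        outputs = c(traj_path, summ_path))
  invisible(list(summary = summ, trajectory = traj_path,
                 recovery = summ_path, manifest = man))
}

#' Scan the feedback exponent and locate the Hopf bifurcation
#'
#' Writes the [gamma_scan()] table as CSV and the located critical
#' exponent as JSON, plus a run manifest. If the critical exponent lies
#' outside the scanned range it is still located and reported as
#' out-of-range.
#'
#' @param params A [friberg_params()] object or a config file path.
#' @param gamma_range Length-2 range of gamma.
#' @param step Grid step.
#' @param outdir Output directory.
#' @return List with `gamma_star`, `in_range`, the scan table, and output
#'   paths, invisibly.
#' @export
run_bifurcation_report <- function(params, gamma_range = c(0, 1), step = 0.01,
                                   outdir) {
  if (is.character(params)) params <- read_model_config(params)
  stopifnot(inherits(params, "friberg_params"))
  if (length(gamma_range) != 2L || gamma_range[1L] < 0 ||
      gamma_range[2L] <= gamma_range[1L])
    stop("`gamma_range` must be an increasing non-negative interval")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  grid <- seq(gamma_range[1L], gamma_range[2L], by = step)
  scan <- gamma_scan(params, grid)
  scan_path <- file.path(outdir, "gamma_scan.csv")
  utils::write.csv(scan, scan_path, row.names = FALSE, quote = FALSE)
  gs <- hopf_gamma(params)
  in_range <- gs >= gamma_range[1L] && gs <= gamma_range[2L]
  gs_path <- file.path(outdir, "gamma_star.json")
  jsonlite::write_json(list(gamma_star = gs, in_range = in_range,
                            n_transit = params$n_transit),
                       gs_path, auto_unbox = TRUE, digits = NA)
  man <- write_manifest(outdir, "bifurcation-scan",
                        config = list(n_transit = params$n_transit,
                                      mtt = params$mtt, circ0 = params$circ0,
                                      gamma_range = gamma_range, step = step),
                        seeds = integer(0),
                        outputs = c(scan_path, gs_path))
  invisible(list(gamma_star = gs, in_range = in_range, scan = scan,
                 scan_csv = scan_path, gamma_star_json = gs_path, manifest = man))
}

#' Run replicated crypt injury simulations and write a report
#'
#' Runs [run_crypt_scenario()] once per seed, writing per-seed time-series
#' and profile CSVs, a cross-seed summary JSON (mean and per-seed recovery
#' times, villus nadir fractions, crypt-count constancy), and a manifest.
#'
#' @param config A [crypt_config()] object or a config file path.
#' @param injury An [injury_spec()] or an injury JSON path.
#' @param seeds Integer vector of replicate seeds.
#' @param outdir Output directory.
#' @param horizon Recorded duration, hours.
#' @return List with the summary and output paths, invisibly.
#' @export
run_crypt_report <- function(config, injury, seeds, outdir, horizon = 264) {
  if (is.character(config)) config <- read_model_config(config)
  if (is.character(injury)) injury <- read_injury(injury)
  stopifnot(inherits(config, "crypt_config"), inherits(injury, "injury_spec"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  rec <- numeric(length(seeds))
  nad <- numeric(length(seeds))
  crypt_const <- logical(length(seeds))
  paths <- character(0)
  for (i in seq_along(seeds)) {
    cfg <- config
    cfg$seed <- as.integer(seeds[i])
    ser <- run_crypt_scenario(cfg, injury, horizon = horizon)
    ts_path <- file.path(outdir, sprintf("series_seed%d.csv", seeds[i]))
    pr_path <- file.path(outdir, sprintf("profile_seed%d.csv", seeds[i]))
    write_crypt_series(ser, ts_path, pr_path)
    rec[i] <- crypt_recovery_time(ser)
    nad[i] <- villus_nadir(ser)$nadir_fraction
    crypt_const[i] <- length(unique(ser$crypt_count)) == 1L
    paths <- c(paths, ts_path, pr_path)
  }
  summ <- list(
    n_seeds = length(seeds),
    recovery_time_h = rec,
    mean_recovery_time_h = mean(rec),
    villus_nadir_fraction = nad,
    mean_villus_nadir_fraction = mean(nad),
    crypt_count_constant = all(crypt_const)
  )
  summ_path <- file.path(outdir, "summary.json")
  jsonlite::write_json(summ, summ_path, auto_unbox = TRUE, digits = NA, null = "null")
  man <- write_manifest(outdir, "simulate-crypt",
                        config = c(unclass(config)[c("n_columns", "n_rows",
                                                     "stem_band", "ta_band",
                                                     "cycle_time_mean",
                                                     "arrested_lifetime")],
                                   list(injury = unclass(injury),
                                        horizon_h = horizon)),
                        seeds = seeds,
                        outputs = c(paths, summ_path))
  invisible(list(summary = summ, summary_json = summ_path,
                 series = paths, manifest = man))
}
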