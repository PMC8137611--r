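#' Standard myelosuppression treatment scenarios
#'
#' The six scenario bundles of the dose-schedule study: feedback exponents
#' gamma in {0.17, 0.3, 0.5} crossed with a single 95% kill of the
#' proliferating pool at t = 0 and with the same kill repeated every
#' 21 days (504 h). All gamma values lie below the Hopf threshold, so each
#' scenario has a stable homeostatic equilibrium. Horizons: 2,160 h
#' (90 days) for single doses, extended to 4,320 h for gamma = 0.5 whose
#' damped oscillations take months to settle; repeated dosing runs
#' `n_cycles` cycles plus one recovery interval.
#'
#' @param gammas Feedback exponents to include.
#' @param kill_fraction Kill fraction applied to the proliferating pool.
#' @param cycle_h Dosing interval for the repeated schedule, hours.
#' @param n_cycles Number of repeated doses.
#' @return List of scenario bundles; each has `name`, `params`
#'   ([friberg_params()]), `schedule` ([treatment_schedule()]), `horizon`
#'   (hours), and `seeds` (empty; the ODE model is deterministic).
#' @examples
#' names(hematology_scenarios())
#' @export
hematology_scenarios <- function(gammas = c(0.17, 0.3, 0.5),
                                 kill_fraction = 0.95,
                                 cycle_h = 21 * 24, n_cycles = 6L) {
  bundles <- list()
  for (g in gammas) {
    p <- friberg_params(gamma = g)
    single_h <- if (g >= 0.5) 4320 else 2160
    bundles[[sprintf("gamma%s_single", format(g))]] <- list(
      name = sprintf("gamma%s_single", format(g)),
      params = p,
      schedule = treatment_schedule(0, kill_fraction),
      horizon = single_h,
      seeds = integer(0)
    )
    bundles[[sprintf("gamma%s_q21d", format(g))]] <- list(
      name = sprintf("gamma%s_q21d", format(g)),
      params = p,
      schedule = treatment_schedule(seq(0, by = cycle_h, length.out = n_cycles),
                                    kill_fraction),
      horizon = n_cycles * cycle_h,
      seeds = integer(0)
    )
  }
  bundles
}

#' Standard crypt injury scenarios
#'
#' The two positional-injury bundles of the crypt study: irreversible
#' cycle arrest of 85% of proliferative cells in the lower (positions
#' 5-12) versus the upper (positions 13-20) half of the TA compartment
#' (positions 5-20), each replicated over distinct seeds.
#'
#' @param n_seeds Replicates per bundle.
#' @param base_seed First seed; replicate seeds are consecutive, with the
#'   two bundles using disjoint ranges.
#' @param arrest_fraction Arrested fraction of proliferative cells.
#' @param injury_time Injury time on the recorded-series clock, hours.
#' @param horizon Recorded duration, hours.
#' @return List of two bundles (`ta_low`, `ta_high`); each has `name`,
#'   `config` ([crypt_config()], seed set per replicate at run time),
#'   `injury` ([injury_spec()]), `horizon`, and `seeds`.
#' @export
crypt_scenarios <- function(n_seeds = 10L, base_seed = 101L,
                            arrest_fraction = 0.85,
                            injury_time = 24, horizon = 264) {
  cfg <- crypt_config()
  list(
    ta_low = list(
      name = "ta_low", config = cfg,
      injury = injury_spec(arrest_fraction, c(5L, 12L), time = injury_time),
      horizon = horizon,
      seeds = seq.int(base_seed, length.out = n_seeds)
    ),
    ta_high = list(
      name = "ta_high", config = cfg,
      injury = injury_spec(arrest_fraction, c(13L, 20L), time = injury_time),
      horizon = horizon,
      seeds = seq.int(base_seed + n_seeds, length.out = n_seeds)
    )
  )
}

#' Noisy observations of a circulating-count trajectory
#'
#' Applies multiplicative lognormal noise with a given coefficient of
#' variation to the circulating-cell series, emulating assay noise on
#' positive, right-skewed counts. The noise has unit mean, so the observed
#' series is unbiased; `cv = 0` returns the input unchanged.
#'
#' @param traj A [simulate_friberg()] trajectory.
#' @param cv Coefficient of variation of the multiplicative noise (>= 0).
#' @param seed RNG seed.
#' @return data.frame with columns `time_h`, `circ`, `observed`.
#' @export
noisy_observations <- function(traj, cv, seed = 1L) {
  stopifnot(inherits(traj, "friberg_trajectory"))
  if (cv < 0) stop("`cv` must be >= 0")
  circ <- traj$states[, "circ"]
  if (cv == 0) return(data.frame(time_h = traj$times, circ = circ, observed = circ))
  sdlog <- sqrt(log1p(cv^2))
  set.seed(seed)
  noise <- stats::rlnorm(length(circ), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  data.frame(time_h = traj$times, circ = circ, observed = circ * noise)
}

#' Materialize scenario bundles as config and schedule files
#'
#' Writes each bundle of [hematology_scenarios()] and [crypt_scenarios()]
#' into its own subdirectory: a model config (JSON) plus a schedule or
#' injury file, and a bundle manifest naming the horizon and seeds. The
#' files round-trip through [read_model_config()], [read_schedule()] and
#' [read_injury()].
#'
#' @param dir Output directory (created if needed).
#' @param hematology,crypt Bundle lists; defaults generate the standard
#'   scenarios.
#' @return Character vector of bundle directories, invisibly.
#' @export
write_scenario_bundles <- function(dir,
                                   hematology = hematology_scenarios(),
                                   crypt = crypt_scenarios()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- character(0)
  for (b in hematology) {
    d <- file.path(dir, b$name)
    dir.create(d, showWarnings = FALSE)
    write_model_config(b$params, file.path(d, "config.json"))
    write_schedule(b$schedule, file.path(d, "schedule.json"))
    jsonlite::write_json(list(name = b$name, horizon_h = b$horizon, seeds = b$seeds),
                         file.path(d, "bundle.json"), auto_unbox = TRUE, digits = NA)
    out <- c(out, d)
  }
  for (b in crypt) {
    d <- file.path(dir, b$name)
    dir.create(d, showWarnings = FALSE)
    write_model_config(b$config, file.path(d, "config.json"))
    write_injury(b$injury, file.path(d, "injury.json"))
    jsonlite::write_json(list(name = b$name, horizon_h = b$horizon, seeds = b$seeds),
                         file.path(d, "bundle.json"), auto_unbox = TRUE, digits = NA)
    out <- c(out, d)
  }
  invisible(out)
}

#' Reload a materialized scenario bundle
#'
#' @param dir A bundle directory written by [write_scenario_bundles()].
#' @return A bundle list in the same shape as the generator output.
#' @export
read_scenario_bundle <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "bundle.json"))
  params <- read_model_config(file.path(dir, "config.json"))
  b <- list(name = meta$name, horizon = meta$horizon_h,
            seeds = as.integer(meta$seeds))
  if (inherits(params, "friberg_params")) {
    b$params <- params
    b$schedule <- read_schedule(file.path(dir, "schedule.json"))
  } else {
    b$config <- params
    b$injury <- read_injury(file.path(dir, "injury.json"))
  }
  b
}
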