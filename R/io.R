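#' Write a simulated trajectory to CSV
#'
#' One row per output grid point with header
#' `time_h, prol, transit_1..transit_n, circ`, optionally followed by a
#' per-time CTCAE neutropenia grade column.
#'
#' @param traj A [simulate_friberg()] trajectory.
#' @param path Output file path.
#' @param grades If `TRUE`, append a `ctcae_grade` column computed from the
#'   circulating count.
#' @param thresholds Grade thresholds passed to [grade_neutropenia()].
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, grades = FALSE,
                             thresholds = c(1.5, 1.0, 0.5, 0.25)) {
  stopifnot(inherits(traj, "friberg_trajectory"))
  df <- data.frame(time_h = traj$times, traj$states, check.names = FALSE)
  if (grades)
    df$ctcae_grade <- grade_neutropenia(pmax(traj$states[, "circ"], 0), thresholds)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a treatment schedule from JSON
#'
#' Expects `{"events": [{"time_h": ..., "kill_fraction": ...}, ...]}`;
#' validates ordering and range via [treatment_schedule()].
#'
#' @param path JSON file path.
#' @return A [treatment_schedule()].
#' @export
read_schedule <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (is.null(x$events)) stop("schedule JSON must contain an `events` field")
  ev <- x$events
  if (length(ev) == 0L || (is.data.frame(ev) && nrow(ev) == 0L))
    return(treatment_schedule())
  if (!all(c("time_h", "kill_fraction") %in% names(ev)))
    stop("each event needs `time_h` and `kill_fraction` fields")
  treatment_schedule(ev$time_h, ev$kill_fraction)
}

#' Write a treatment schedule to JSON
#'
#' @param schedule A [treatment_schedule()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "treatment_schedule"))
  jsonlite::write_json(
    list(events = data.frame(time_h = schedule$time_h,
                             kill_fraction = schedule$kill_fraction)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a crypt injury specification from JSON
#'
#' Expects `{"arrest_fraction": ..., "band": [lo, hi], "time_h": ...}`.
#'
#' @param path JSON file path.
#' @return An [injury_spec()].
#' @export
read_injury <- function(path) {
  x <- jsonlite::fromJSON(path)
  for (f in c("arrest_fraction", "band"))
    if (is.null(x[[f]])) stop(sprintf("injury JSON must contain `%s`", f))
  injury_spec(x$arrest_fraction, x$band,
              time = if (is.null(x$time_h)) 24 else x$time_h,
              exact = isTRUE(x$exact))
}

#' Write a crypt injury specification to JSON
#'
#' @param injury An [injury_spec()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_injury <- function(injury, path) {
  stopifnot(inherits(injury, "injury_spec"))
  jsonlite::write_json(
    list(arrest_fraction = injury$arrest_fraction, band = injury$band,
         time_h = injury$time, exact = injury$exact),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read model configuration from YAML or JSON
#'
#' A `model: hematology` (or `kind: friberg`) config maps to
#' [friberg_params()]; a `model: crypt` config maps to [crypt_config()].
#' Unknown fields are rejected. The format is chosen by file extension
#' (`.yaml`/`.yml` vs `.json`).
#'
#' @param path Config file path.
#' @return A `friberg_params` or `crypt_config` object.
#' @export
read_model_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path)
  }
  model <- x$model
  if (is.null(model)) stop("config must contain a `model` field (hematology | crypt)")
  x$model <- NULL
  ctor <- switch(model,
                 hematology = , friberg = friberg_params,
                 crypt = crypt_config,
                 stop(sprintf("unknown model `%s`", model)))
  allowed <- names(formals(ctor))
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop(sprintf("unknown config field(s): %s", paste(bad, collapse = ", ")))
  if (identical(ctor, crypt_config)) {
    for (f in c("stem_band", "ta_band")) if (!is.null(x[[f]])) x[[f]] <- unlist(x[[f]])
  }
  do.call(ctor, x)
}

#' Write model configuration to YAML or JSON
#'
#' @param params A `friberg_params` or `crypt_config` object.
#' @param path Output file path; extension selects the format.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(params, path) {
  if (inherits(params, "friberg_params")) {
    x <- c(list(model = "hematology"),
           params[c("circ0", "mtt", "gamma", "n_transit")])
  } else if (inherits(params, "crypt_config")) {
    x <- c(list(model = "crypt"), unclass(params))
    x$villus_shed_rate <- x$villus_shed_rate  # may be NULL -> dropped below
    x <- x[!vapply(x, is.null, logical(1))]
  } else stop("unsupported parameter object")
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Write a crypt time series and proliferation profile to CSV
#'
#' The time series file has header
#' `time_h, crypt_cells, villus_cells, ta_proliferative_cells`. The
#' optional profile file is a matrix of cycling-cell fractions, one row
#' per time point and one column per crypt position.
#'
#' @param series A [run_crypt_scenario()] result.
#' @param path Time-series CSV path.
#' @param profile_path Optional profile CSV path.
#' @return `path`, invisibly.
#' @export
write_crypt_series <- function(series, path, profile_path = NULL) {
  stopifnot(inherits(series, "crypt_series"))
  df <- data.frame(time_h = series$times,
                   crypt_cells = series$crypt_count,
                   villus_cells = series$villus_count,
                   ta_proliferative_cells = series$ta_proliferative_count)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(profile_path)) {
    pdf_ <- data.frame(time_h = series$times, series$prolif_profile,
                       check.names = FALSE)
    utils::write.csv(pdf_, profile_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
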