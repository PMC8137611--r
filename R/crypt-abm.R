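# Cell-state codes on the lattice
CELL_EMPTY <- 0L
CELL_STEM <- 1L
CELL_PROLIF <- 2L
CELL_DIFF <- 3L
CELL_ARRESTED <- 4L

#' Configuration of the agent-based crypt-villus model
#'
#' The crypt is a cylindrical lattice of `n_columns` cell columns by
#' `n_rows` positions (0-based, counted from the crypt base). Stem cells
#' occupy `stem_band`; the transit-amplifying (TA) compartment of rapidly
#' cycling progenitors occupies `ta_band` (positions 5-20 by default);
#' cells pushed above the TA band differentiate. The villus is modelled as
#' a well-mixed cell-count compartment fed by cells evicted from the crypt
#' top and depleted by shedding at a constant rate.
#'
#' @param n_columns Cells per ring (> 0).
#' @param n_rows Crypt height in cell positions (> 0).
#' @param stem_band Inclusive position interval `c(lo, hi)` of the stem
#'   niche at the base.
#' @param ta_band Inclusive position interval of the TA compartment; must
#'   lie above `stem_band` and within `[0, n_rows)`.
#' @param cycle_time_mean Mean TA cell cycle time, hours.
#' @param cycle_time_jitter Half-width of the uniform jitter on TA cycle
#'   times, as a fraction of the mean.
#' @param stem_cycle_time Stem cell cycle time, hours.
#' @param arrested_lifetime Time from cycle arrest to senescence-driven
#'   removal, hours (comparable to absorptive epithelial cell lifetime).
#' @param villus_init Initial villus cell count.
#' @param villus_shed_rate Villus shedding rate, cells/hour; `NULL` means
#'   calibrate during burn-in to the measured crypt-to-villus influx.
#' @param seed RNG seed giving deterministic runs.
#' @return Object of class `crypt_config`.
#' @export
crypt_config <- function(n_columns = 16L, n_rows = 30L,
                         stem_band = c(0L, 4L), ta_band = c(5L, 20L),
                         cycle_time_mean = 21.5, cycle_time_jitter = 0.2,
                         stem_cycle_time = 24,
                         arrested_lifetime = 72,
                         villus_init = 3500, villus_shed_rate = NULL,
                         seed = 1L) {
  n_columns <- as.integer(n_columns); n_rows <- as.integer(n_rows)
  stem_band <- as.integer(stem_band); ta_band <- as.integer(ta_band)
  if (n_columns < 1L || n_rows < 1L) stop("lattice dimensions must be positive")
  if (length(stem_band) != 2L || length(ta_band) != 2L)
    stop("bands must be length-2 position intervals c(lo, hi)")
  if (stem_band[1L] > stem_band[2L] || ta_band[1L] > ta_band[2L])
    stop("band intervals must satisfy lo <= hi")
  if (stem_band[2L] >= ta_band[1L]) stop("`stem_band` must lie below `ta_band`")
  if (ta_band[1L] < 0L || ta_band[2L] >= n_rows)
    stop("`ta_band` must lie within [0, n_rows)")
  if (cycle_time_mean <= 0 || stem_cycle_time <= 0 || arrested_lifetime <= 0)
    stop("all times must be positive")
  if (cycle_time_jitter < 0 || cycle_time_jitter >= 1)
    stop("`cycle_time_jitter` must be in [0, 1)")
  if (villus_init <= 0) stop("`villus_init` must be positive")
  structure(
    list(n_columns = n_columns, n_rows = n_rows,
         stem_band = stem_band, ta_band = ta_band,
         cycle_time_mean = cycle_time_mean, cycle_time_jitter = cycle_time_jitter,
         stem_cycle_time = stem_cycle_time,
         arrested_lifetime = arrested_lifetime,
         villus_init = villus_init, villus_shed_rate = villus_shed_rate,
         seed = as.integer(seed)),
    class = "crypt_config"
  )
}

#' Positional cycle-arrest injury specification
#'
#' An irreversible cycle arrest applied to proliferative cells within a
#' positional sub-band of the TA compartment. Arrested cells keep their
#' lattice sites, are pushed upwards like any cell, never divide and never
#' revert; they are removed at senescence if still in the crypt.
#'
#' @param arrest_fraction Probability that each proliferative cell in the
#'   band is arrested (in `[0, 1]`).
#' @param band Inclusive position interval `c(lo, hi)` targeted; must lie
#'   within the configured TA band.
#' @param time Injury time, hours, on the recorded-series clock.
#' @param exact If `TRUE`, arrest exactly `round(arrest_fraction * n)` of
#'   the `n` eligible cells (sampled without replacement) instead of
#'   independent per-cell Bernoulli draws.
#' @return Object of class `injury_spec`.
#' @examples
#' injury_spec(0.85, band = c(5, 12))   # low TA band
#' injury_spec(0.85, band = c(13, 20))  # high TA band
#' @export
injury_spec <- function(arrest_fraction, band, time = 24, exact = FALSE) {
  if (arrest_fraction < 0 || arrest_fraction > 1)
    stop("`arrest_fraction` must be in [0, 1]")
  band <- as.integer(band)
  if (length(band) != 2L || band[1L] > band[2L]) stop("`band` must be c(lo, hi)")
  if (time < 0) stop("`time` must be >= 0")
  structure(list(arrest_fraction = arrest_fraction, band = band,
                 time = time, exact = isTRUE(exact)),
            class = "injury_spec")
}

# cycle time draw for a newborn cell at 0-based position `pos`
.crypt_new_clock <- function(cfg, pos) {
  if (pos >= cfg$stem_band[1L] && pos <= cfg$stem_band[2L]) {
    cfg$stem_cycle_time
  } else {
    cfg$cycle_time_mean * stats::runif(1, 1 - cfg$cycle_time_jitter,
                                       1 + cfg$cycle_time_jitter)
  }
}

# state code implied by a 0-based position (healthy lineage)
.crypt_pos_state <- function(cfg, pos) {
  if (pos <= cfg$stem_band[2L]) CELL_STEM
  else if (pos <= cfg$ta_band[2L]) CELL_PROLIF
  else CELL_DIFF
}

# re-type the cycling cells of one column after an upward push:
# stem pushed into the TA band becomes proliferative, cycling cells pushed
# above the TA band differentiate; arrested and empty sites are untouched
.crypt_retype_column <- function(st, col) {
  cfg <- st$config
  ta_lo <- cfg$ta_band[1L] + 1L; ta_hi <- cfg$ta_band[2L] + 1L
  s <- st$state[, col]
  in_ta <- seq_along(s) >= ta_lo & seq_along(s) <= ta_hi
  above <- seq_along(s) > ta_hi
  promote <- which(s == CELL_STEM & in_ta)
  if (length(promote)) st$state[promote, col] <- CELL_PROLIF
  differ <- which((s == CELL_STEM | s == CELL_PROLIF) & above)
  if (length(differ)) {
    st$state[differ, col] <- CELL_DIFF
    st$clock[differ, col] <- NA_real_
  }
  st
}

#' Initialize a crypt to homeostasis
#'
#' Builds a fully occupied lattice (stem cells in the stem band, TA
#' progenitors in the TA band, differentiated cells above) with cycle
#' clocks drawn uniformly over each cell's cycle time, then runs a burn-in
#' during which the crypt-to-villus influx is measured. If the shedding
#' rate is not supplied it is calibrated to that influx so that the villus
#' is in balance. The returned state has its clock at 0 h and the villus
#' at `villus_init`.
#'
#' Runs are deterministic in `config$seed`: the full RNG stream of the
#' simulation is seeded here.
#'
#' @param config A [crypt_config()] object.
#' @param burn_in Burn-in duration, hours.
#' @param dt Time step, hours.
#' @return Object of class `crypt_state`.
#' @export
init_crypt <- function(config, burn_in = 48, dt = 0.5) {
  stopifnot(inherits(config, "crypt_config"))
  set.seed(config$seed)
  nr <- config$n_rows; nc <- config$n_columns
  pos <- seq_len(nr) - 1L
  state <- matrix(vapply(pos, function(p) .crypt_pos_state(config, p), integer(1)),
                  nrow = nr, ncol = nc)
  clock <- matrix(NA_real_, nr, nc)
  for (col in seq_len(nc)) {
    for (r in seq_len(nr)) {
      if (state[r, col] %in% c(CELL_STEM, CELL_PROLIF)) {
        ct <- .crypt_new_clock(config, r - 1L)
        clock[r, col] <- stats::runif(1, 0, ct)
      }
    }
  }
  st <- structure(
    list(config = config, state = state, clock = clock,
         arrest_age = matrix(NA_real_, nr, nc),
         villus = config$villus_init,
         time = 0, transfers_total = 0, shed_total = 0,
         removals_total = 0L, floor_shed = 0),
    class = "crypt_state"
  )
  # burn-in with shedding suspended, to measure the division-driven influx
  st_cal <- st
  st_cal$config$villus_shed_rate <- 0
  steps <- max(1L, round(burn_in / dt))
  for (i in seq_len(steps)) st_cal <- crypt_step(st_cal, dt)
  influx <- st_cal$transfers_total / (steps * dt)
  st_cal$config <- config
  if (is.null(config$villus_shed_rate))
    st_cal$config$villus_shed_rate <- influx
  st_cal$time <- 0
  st_cal$villus <- config$villus_init
  st_cal$transfers_total <- 0
  st_cal$shed_total <- 0
  st_cal$removals_total <- 0L
  st_cal
}

#' Advance the crypt-villus state by one time step
#'
#' One step performs, in order: (i) divisions of cycling (stem and
#' proliferative) cells whose clock elapses, processed in random order —
#' the daughter is inserted at the mother's site and the mother's column
#' is pushed up by one row from that site, the cell leaving the top row
#' transferring to the villus; (ii) position-based fate changes of pushed
#' cells (stem entering the TA band become proliferative, cycling cells
#' above it differentiate); (iii) removal of arrested cells reaching
#' senescence, the column above collapsing down by one and leaving an
#' empty top site refilled by subsequent pushes (evicting an empty site
#' transfers nothing to the villus); (iv) villus shedding at the
#' configured rate.
#'
#' @param state A `crypt_state`.
#' @param dt Time step, hours; must not exceed one tenth of the shortest
#'   possible cycle time.
#' @return The advanced `crypt_state`.
#' @export
crypt_step <- function(state, dt = 0.5) {
  stopifnot(inherits(state, "crypt_state"))
  cfg <- state$config
  min_cycle <- min(cfg$stem_cycle_time,
                   cfg$cycle_time_mean * (1 - cfg$cycle_time_jitter))
  if (dt > min_cycle / 10)
    stop(sprintf("`dt` must be <= min cycle time / 10 (%.3g h)", min_cycle / 10))
  nr <- cfg$n_rows
  cycling <- state$state == CELL_STEM | state$state == CELL_PROLIF
  state$clock[cycling] <- state$clock[cycling] - dt

  # (i)+(ii) divisions in random order; due set re-scanned after each push
  repeat {
    due <- which((state$state == CELL_STEM | state$state == CELL_PROLIF) &
                   !is.na(state$clock) & state$clock <= 0)
    if (length(due) == 0L) break
    idx <- if (length(due) == 1L) due else sample(due, 1L)
    r <- (idx - 1L) %% nr + 1L
    col <- (idx - 1L) %/% nr + 1L
    evicted <- state$state[nr, col]
    if (r < nr) {
      shift <- r:(nr - 1L)
      state$state[shift + 1L, col] <- state$state[shift, col]
      state$clock[shift + 1L, col] <- state$clock[shift, col]
      state$arrest_age[shift + 1L, col] <- state$arrest_age[shift, col]
    }
    # daughter at the mother's site; mother (now at r + 1, if still in the
    # crypt) gets a fresh clock for its new position
    state$state[r, col] <- .crypt_pos_state(cfg, r - 1L)
    state$clock[r, col] <- .crypt_new_clock(cfg, r - 1L)
    state$arrest_age[r, col] <- NA_real_
    if (r < nr && (state$state[r + 1L, col] %in% c(CELL_STEM, CELL_PROLIF)))
      state$clock[r + 1L, col] <- .crypt_new_clock(cfg, r)
    state <- .crypt_retype_column(state, col)
    if (evicted != CELL_EMPTY) {
      state$villus <- state$villus + 1
      state$transfers_total <- state$transfers_total + 1
    }
  }

  # (iii) senescence of arrested cells
  arrested <- state$state == CELL_ARRESTED
  state$arrest_age[arrested] <- state$arrest_age[arrested] + dt
  repeat {
    due <- which(state$state == CELL_ARRESTED &
                   state$arrest_age >= cfg$arrested_lifetime)
    if (length(due) == 0L) break
    idx <- if (length(due) == 1L) due else sample(due, 1L)
    r <- (idx - 1L) %% nr + 1L
    col <- (idx - 1L) %/% nr + 1L
    if (r < nr) {
      shift <- r:(nr - 1L)
      state$state[shift, col] <- state$state[shift + 1L, col]
      state$clock[shift, col] <- state$clock[shift + 1L, col]
      state$arrest_age[shift, col] <- state$arrest_age[shift + 1L, col]
    }
    state$state[nr, col] <- CELL_EMPTY
    state$clock[nr, col] <- NA_real_
    state$arrest_age[nr, col] <- NA_real_
    state$removals_total <- state$removals_total + 1L
  }

  # (iv) villus shedding
  shed <- min(cfg$villus_shed_rate * dt, state$villus)
  state$villus <- state$villus - shed
  state$shed_total <- state$shed_total + shed
  state$time <- state$time + dt
  state
}

#' Apply a positional cycle-arrest injury
#'
#' Each proliferative cell whose position lies in the injury band becomes
#' arrested, independently with probability `arrest_fraction` (or as an
#' exact fraction if the injury requests it). Stem cells and cells outside
#' the band are untouched. Arrest is irreversible.
#'
#' @param state A `crypt_state`.
#' @param injury An [injury_spec()].
#' @return The injured `crypt_state`.
#' @export
apply_injury <- function(state, injury) {
  stopifnot(inherits(state, "crypt_state"), inherits(injury, "injury_spec"))
  cfg <- state$config
  if (injury$band[1L] < cfg$ta_band[1L] || injury$band[2L] > cfg$ta_band[2L])
    stop("injury band must lie within the TA band")
  rows <- (injury$band[1L]:injury$band[2L]) + 1L
  eligible <- which(state$state[rows, , drop = FALSE] == CELL_PROLIF)
  if (length(eligible) == 0L || injury$arrest_fraction == 0) return(state)
  hit <- if (injury$exact) {
    n_hit <- round(injury$arrest_fraction * length(eligible))
    if (n_hit == 0L) integer(0) else sample(eligible, n_hit)
  } else {
    eligible[stats::runif(length(eligible)) < injury$arrest_fraction]
  }
  if (length(hit)) {
    sub_state <- state$state[rows, , drop = FALSE]
    sub_clock <- state$clock[rows, , drop = FALSE]
    sub_age <- state$arrest_age[rows, , drop = FALSE]
    sub_state[hit] <- CELL_ARRESTED
    sub_clock[hit] <- NA_real_
    sub_age[hit] <- 0
    state$state[rows, ] <- sub_state
    state$clock[rows, ] <- sub_clock
    state$arrest_age[rows, ] <- sub_age
  }
  state
}

# occupied-site count of the lattice
crypt_cell_count <- function(state) sum(state$state != CELL_EMPTY)

# proliferative cells within the TA band
ta_proliferative_count <- function(state) {
  rows <- (state$config$ta_band[1L]:state$config$ta_band[2L]) + 1L
  sum(state$state[rows, ] == CELL_PROLIF)
}

# per-row fraction of cycling (stem or proliferative) cells
row_proliferative_fraction <- function(state) {
  cyc <- state$state == CELL_STEM | state$state == CELL_PROLIF
  rowMeans(cyc)
}

#' Run a crypt injury scenario
#'
#' Initializes the crypt to homeostasis (burn-in), records the state on a
#' regular output grid, applies the injury at its specified time, and runs
#' to the horizon. The recorded series clock starts at 0 h at the end of
#' burn-in; the injury is applied before the state at the injury time is
#' recorded. Deterministic in `config$seed`.
#'
#' @param config A [crypt_config()].
#' @param injury An [injury_spec()], or `NULL` for an uninjured run.
#' @param horizon Recorded duration, hours; must exceed the injury time.
#' @param dt Time step, hours.
#' @param output_step Recording interval, hours (a multiple of `dt`).
#' @param burn_in Burn-in duration, hours.
#' @return Object of class `crypt_series`: list with `times`,
#'   `crypt_count`, `villus_count`, `ta_proliferative_count`,
#'   `prolif_profile` (time x position matrix of cycling-cell fractions),
#'   `reference_ta` (pre-injury mean TA proliferative count), `injury`,
#'   `config`, and flux totals (`transfers_total`, `shed_total`,
#'   `removals_total`).
#' @examples
#' \donttest{
#' cfg <- crypt_config(seed = 7)
#' ser <- run_crypt_scenario(cfg, injury_spec(0.85, c(5, 12)), horizon = 264)
#' crypt_recovery_time(ser)
#' }
#' @export
run_crypt_scenario <- function(config, injury = NULL, horizon = 264,
                               dt = 0.5, output_step = 1, burn_in = 48) {
  stopifnot(inherits(config, "crypt_config"))
  if (!is.null(injury)) {
    stopifnot(inherits(injury, "injury_spec"))
    if (horizon <= injury$time) stop("`horizon` must exceed the injury time")
  }
  steps_per_out <- round(output_step / dt)
  if (abs(steps_per_out * dt - output_step) > 1e-9)
    stop("`output_step` must be a multiple of `dt`")
  st <- init_crypt(config, burn_in = burn_in, dt = dt)
  times <- seq(0, horizon, by = output_step)
  n_out <- length(times)
  crypt_count <- numeric(n_out)
  villus_count <- numeric(n_out)
  ta_count <- numeric(n_out)
  profile <- matrix(NA_real_, n_out, config$n_rows,
                    dimnames = list(NULL, paste0("pos_", seq_len(config$n_rows) - 1L)))
  injured <- is.null(injury)
  record <- function(i) {
    crypt_count[i] <<- crypt_cell_count(st)
    villus_count[i] <<- st$villus
    ta_count[i] <<- ta_proliferative_count(st)
    profile[i, ] <<- row_proliferative_fraction(st)
  }
  for (i in seq_len(n_out)) {
    if (!injured && times[i] >= injury$time) {
      st <- apply_injury(st, injury)
      injured <- TRUE
    }
    record(i)
    if (i < n_out) for (s in seq_len(steps_per_out)) st <- crypt_step(st, dt)
  }
  pre <- if (is.null(injury)) rep(TRUE, n_out) else times < injury$time
  reference_ta <- if (any(pre)) mean(ta_count[pre]) else NA_real_
  structure(
    list(times = times, crypt_count = crypt_count, villus_count = villus_count,
         ta_proliferative_count = ta_count, prolif_profile = profile,
         reference_ta = reference_ta, injury = injury, config = config,
         transfers_total = st$transfers_total, shed_total = st$shed_total,
         removals_total = st$removals_total,
         villus_final = st$villus),
    class = "crypt_series"
  )
}

#' @export
print.crypt_series <- function(x, ...) {
  cat(sprintf("Crypt-villus time series: %d points over [%g, %g] h\n",
              length(x$times), min(x$times), max(x$times)))
  if (!is.null(x$injury))
    cat(sprintf("  injury: %.0f%% arrest at positions %d-%d, t = %g h\n",
                100 * x$injury$arrest_fraction, x$injury$band[1L],
                x$injury$band[2L], x$injury$time))
  cat(sprintf("  crypt cells: %g-%g; villus: %.0f-%.0f; TA proliferative: %g-%g\n",
              min(x$crypt_count), max(x$crypt_count),
              min(x$villus_count), max(x$villus_count),
              min(x$ta_proliferative_count), max(x$ta_proliferative_count)))
  invisible(x)
}

#' Recovery time of the TA compartment after an injury
#'
#' First time after the injury at which the TA proliferative count returns
#' to within `tolerance_fraction` of the reference level and remains there
#' for at least `hold` hours, reported in hours since the injury. `NA` if
#' no such time exists within the recorded horizon.
#'
#' @param series A [run_crypt_scenario()] result containing an injury.
#' @param reference_level Homeostatic TA proliferative count; defaults to
#'   the series' pre-injury mean.
#' @param tolerance_fraction Band half-width as a fraction of the reference.
#' @param hold Time the count must remain in the band, hours.
#' @return Recovery time in hours since the injury, or `NA_real_`.
#' @export
crypt_recovery_time <- function(series, reference_level = NULL,
                                tolerance_fraction = 0.1, hold = 12) {
  stopifnot(inherits(series, "crypt_series"))
  if (is.null(series$injury)) stop("series contains no injury")
  ref <- if (is.null(reference_level)) series$reference_ta else reference_level
  if (!is.finite(ref) || ref <= 0) stop("no valid reference level")
  t_inj <- series$injury$time
  idx <- which(series$times >= t_inj)
  ok <- abs(series$ta_proliferative_count[idx] - ref) <= tolerance_fraction * ref
  tt <- series$times[idx]
  for (i in seq_along(idx)) {
    if (!ok[i]) next
    if (tt[i] + hold > max(tt)) return(NA_real_)  # hold window exceeds horizon
    win <- tt >= tt[i] & tt <= tt[i] + hold
    if (all(ok[win])) return(tt[i] - t_inj)
  }
  NA_real_
}

#' Villus nadir relative to its pre-injury mean
#'
#' Minimum villus cell count after the injury, as a fraction of the mean
#' villus count before the injury.
#'
#' @param series A [run_crypt_scenario()] result containing an injury.
#' @return List with `nadir` (cells), `nadir_time` (h), `pre_mean` (cells),
#'   and `nadir_fraction` (nadir / pre-injury mean).
#' @export
villus_nadir <- function(series) {
  stopifnot(inherits(series, "crypt_series"))
  if (is.null(series$injury)) stop("series contains no injury")
  pre <- series$times < series$injury$time
  if (!any(pre)) stop("series has no pre-injury window")
  pre_mean <- mean(series$villus_count[pre])
  post <- which(series$times >= series$injury$time)
  i <- post[which.min(series$villus_count[post])]
  list(nadir = series$villus_count[i], nadir_time = series$times[i],
       pre_mean = pre_mean, nadir_fraction = series$villus_count[i] / pre_mean)
}
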