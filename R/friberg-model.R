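#' Parameters of the transit-compartment myelosuppression model
#'
#' Constructs the parameter set of the classical five-compartment model of
#' chemotherapy-induced myelosuppression: a proliferating progenitor pool,
#' `n_transit` non-proliferating maturation compartments, and a circulating
#' mature-cell pool. A feedback term \eqn{(Circ_0/Circ)^\gamma} stimulates
#' proliferation when circulating counts fall below baseline. All first-order
#' rate constants (proliferation, transit, elimination) equal
#' \eqn{k = (n_{transit}+1)/MTT}.
#'
#' Defaults are the canonical human neutrophil parametrization:
#' baseline 5.05 x 10^9 cells/L, mean transit time 125 h, gamma 0.17,
#' three transit compartments.
#'
#' @param circ0 Baseline circulating cell concentration, 10^9 cells/L (> 0).
#' @param mtt Mean transit time through the maturation chain, hours (> 0).
#' @param gamma Feedback exponent, dimensionless (>= 0).
#' @param n_transit Number of transit compartments, positive integer.
#' @return An object of class `friberg_params`: a list with the supplied
#'   fields plus the derived common rate constant `k = (n_transit + 1) / mtt`
#'   (per hour) and the compartment names.
#' @examples
#' p <- friberg_params(gamma = 0.3)
#' p$k  # (3 + 1) / 125 per hour
#' @export
friberg_params <- function(circ0 = 5.05, mtt = 125, gamma = 0.17, n_transit = 3L) {
  if (!is.numeric(circ0) || length(circ0) != 1L || !is.finite(circ0) || circ0 <= 0)
    stop("`circ0` must be a single positive number (10^9 cells/L)")
  if (!is.numeric(mtt) || length(mtt) != 1L || !is.finite(mtt) || mtt <= 0)
    stop("`mtt` must be a single positive number (hours)")
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) || gamma < 0)
    stop("`gamma` must be a single non-negative number")
  n_transit <- as.integer(n_transit)
  if (is.na(n_transit) || n_transit < 1L)
    stop("`n_transit` must be a positive integer")
  structure(
    list(
      circ0 = circ0, mtt = mtt, gamma = gamma, n_transit = n_transit,
      k = (n_transit + 1) / mtt,
      state_names = c("prol", paste0("transit_", seq_len(n_transit)), "circ")
    ),
    class = "friberg_params"
  )
}

#' @export
print.friberg_params <- function(x, ...) {
  cat("Transit-compartment myelosuppression model parameters\n")
  cat(sprintf("  circ0     : %g x 10^9 cells/L\n", x$circ0))
  cat(sprintf("  mtt       : %g h\n", x$mtt))
  cat(sprintf("  gamma     : %g\n", x$gamma))
  cat(sprintf("  n_transit : %d  (k = %g per h)\n", x$n_transit, x$k))
  invisible(x)
}

#' Homeostatic equilibrium of the myelosuppression model
#'
#' With equal proliferation, transit, and elimination rate constants the
#' unique positive equilibrium has every compartment at the circulating
#' baseline `circ0`.
#'
#' @param params A [friberg_params()] object.
#' @return Named numeric vector of length `n_transit + 2`, all entries
#'   equal to `circ0`.
#' @export
steady_state <- function(params) {
  stopifnot(inherits(params, "friberg_params"))
  stats::setNames(rep(params$circ0, params$n_transit + 2L), params$state_names)
}

#' Right-hand side of the myelosuppression ODE system
#'
#' Instantaneous derivatives of the model
#' \deqn{Prol' = k\,Prol\,(Circ_0/Circ)^\gamma - k\,Prol}
#' \deqn{T_1' = k(Prol - T_1),\; \ldots,\; Circ' = k(T_n - Circ).}
#' The feedback term requires a positive circulating count; during
#' integration `circ` is floored at `floor_frac * circ0` and any activation
#' of the floor is counted (see [simulate_friberg()]).
#'
#' @param state Named or unnamed numeric state vector
#'   `(prol, transit_1..transit_n, circ)`, 10^9 cells/L.
#' @param params A [friberg_params()] object.
#' @param floor_frac Fraction of `circ0` used as a positivity floor inside
#'   the feedback term only.
#' @return Numeric derivative vector of the same length as `state`.
#' @export
friberg_rhs <- function(state, params, floor_frac = 1e-12) {
  stopifnot(inherits(params, "friberg_params"))
  n <- params$n_transit
  if (length(state) != n + 2L)
    stop(sprintf("`state` must have length %d", n + 2L))
  k <- params$k
  circ <- state[n + 2L]
  if (circ <= 0 && floor_frac <= 0)
    stop("feedback term undefined for circ <= 0")
  circ_eff <- max(circ, floor_frac * params$circ0)
  feedback <- (params$circ0 / circ_eff)^params$gamma
  d <- numeric(n + 2L)
  d[1L] <- k * state[1L] * feedback - k * state[1L]
  d[2L:(n + 1L)] <- k * (state[1L:n] - state[2L:(n + 1L)])
  d[n + 2L] <- k * (state[n + 1L] - state[n + 2L])
  d
}

#' Fractional-kill treatment schedule
#'
#' An ordered sequence of instantaneous dose events. At each event time the
#' proliferating pool is multiplied by `1 - kill_fraction`; no other
#' compartment is touched. Events supplied at the same time are composed
#' multiplicatively into a single event with fraction
#' `1 - (1 - f1)(1 - f2)`.
#'
#' @param times Event times, hours, >= 0, non-decreasing (sorted if not).
#' @param kill_fractions Kill fractions in `[0, 1]`, recycled to
#'   `length(times)`.
#' @return Object of class `treatment_schedule`: a data.frame with columns
#'   `time_h` (strictly increasing) and `kill_fraction`.
#' @examples
#' treatment_schedule(0, 0.95)                      # single 95% kill
#' treatment_schedule(seq(0, 5 * 504, by = 504), 0.95)  # q21d x 6
#' @export
treatment_schedule <- function(times = numeric(0), kill_fractions = numeric(0)) {
  if (length(times) == 0L) {
    ev <- data.frame(time_h = numeric(0), kill_fraction = numeric(0))
    return(structure(ev, class = c("treatment_schedule", "data.frame")))
  }
  kill_fractions <- rep_len(kill_fractions, length(times))
  if (any(!is.finite(times)) || any(times < 0))
    stop("event times must be finite and >= 0")
  if (any(!is.finite(kill_fractions)) || any(kill_fractions < 0) || any(kill_fractions > 1))
    stop("kill fractions must lie in [0, 1]")
  o <- order(times)
  times <- times[o]; kill_fractions <- kill_fractions[o]
  # compose simultaneous events: survival fractions multiply
  surv <- tapply(1 - kill_fractions, times, prod)
  ev <- data.frame(time_h = as.numeric(names(surv)), kill_fraction = 1 - as.numeric(surv))
  ev <- ev[order(ev$time_h), , drop = FALSE]
  rownames(ev) <- NULL
  structure(ev, class = c("treatment_schedule", "data.frame"))
}

#' Simulate the myelosuppression model under a treatment schedule
#'
#' Integrates the system piecewise between dose events with a stiff-capable
#' adaptive integrator (lsoda, stop-and-restart at each event). At an event
#' the proliferating pool is reduced instantaneously by the event's kill
#' fraction; the trajectory is continuous elsewhere. The initial condition
#' defaults to the homeostatic equilibrium.
#'
#' @param params A [friberg_params()] object.
#' @param schedule A [treatment_schedule()] (or `NULL` for no treatment).
#' @param horizon Simulation horizon, hours; must exceed the last event time.
#' @param dt_out Output grid step, hours (event times are always included).
#' @param init Optional initial state vector; defaults to [steady_state()].
#' @param rtol,atol Relative and absolute integrator tolerances.
#' @param floor_frac Positivity floor for the feedback term, as a fraction
#'   of `circ0`; activations are counted and reported via a warning and the
#'   `floor_activations` field.
#' @return Object of class `friberg_trajectory`: list with `times` (hours),
#'   `states` (matrix, one row per time, columns
#'   `prol, transit_1..transit_n, circ`), `params`, `schedule`, and
#'   `floor_activations`. State values at an event time are post-dose.
#' @examples
#' p <- friberg_params(gamma = 0.17)
#' tr <- simulate_friberg(p, treatment_schedule(0, 0.95), horizon = 2160)
#' min(tr$states[, "circ"])  # nadir
#' @export
simulate_friberg <- function(params, schedule = NULL, horizon, dt_out = 1,
                             init = NULL, rtol = 1e-8, atol = 1e-10,
                             floor_frac = 1e-12) {
  stopifnot(inherits(params, "friberg_params"))
  if (is.null(schedule)) schedule <- treatment_schedule()
  stopifnot(inherits(schedule, "treatment_schedule"))
  if (!is.numeric(horizon) || horizon <= 0) stop("`horizon` must be positive")
  ev <- schedule[schedule$kill_fraction > 0, , drop = FALSE]  # zero-kill events are no-ops
  if (nrow(ev) > 0 && horizon <= max(ev$time_h))
    stop("`horizon` must exceed the last event time")
  y <- if (is.null(init)) steady_state(params) else {
    if (length(init) != params$n_transit + 2L) stop("`init` has the wrong length")
    stats::setNames(as.numeric(init), params$state_names)
  }

  floor_env <- new.env(parent = emptyenv())
  floor_env$n <- 0L
  deriv_fun <- function(t, y, parms) {
    circ <- y[length(y)]
    if (circ < floor_frac * params$circ0) floor_env$n <- floor_env$n + 1L
    list(friberg_rhs(y, params, floor_frac = floor_frac))
  }

  bounds <- sort(unique(c(0, ev$time_h[ev$time_h > 0 & ev$time_h < horizon], horizon)))
  ev_at <- function(t) ev$kill_fraction[abs(ev$time_h - t) < 1e-9]

  all_times <- numeric(0)
  all_states <- NULL
  for (s in seq_len(length(bounds) - 1L)) {
    t0 <- bounds[s]; t1 <- bounds[s + 1L]
    f <- ev_at(t0)
    if (length(f) == 1L) y["prol"] <- y["prol"] * (1 - f)
    grid <- unique(c(seq(t0, t1, by = dt_out), t1))
    sol <- deSolve::ode(y = y, times = grid, func = deriv_fun, parms = NULL,
                        method = "lsoda", rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1L] < 0)
      stop(sprintf("integration failed on [%g, %g] h", t0, t1))
    seg_states <- unname(sol[, -1L, drop = FALSE])
    seg_states[seg_states < 0 & seg_states > -atol * 10] <- 0
    keep <- if (s == 1L) seq_len(nrow(sol)) else seq(2L, nrow(sol))
    all_times <- c(all_times, sol[keep, 1L])
    all_states <- rbind(all_states, seg_states[keep, , drop = FALSE])
    y <- stats::setNames(seg_states[nrow(seg_states), ], params$state_names)
  }
  colnames(all_states) <- params$state_names
  if (floor_env$n > 0L)
    warning(sprintf("feedback positivity floor activated %d times", floor_env$n))
  structure(
    list(times = all_times, states = all_states, params = params,
         schedule = schedule, floor_activations = floor_env$n),
    class = "friberg_trajectory"
  )
}

#' @export
print.friberg_trajectory <- function(x, ...) {
  cat(sprintf("Myelosuppression trajectory: %d time points over [%g, %g] h, %d dose event(s)\n",
              length(x$times), min(x$times), max(x$times), nrow(x$schedule)))
  cat(sprintf("  circ range: [%.4g, %.4g] x 10^9 cells/L (baseline %g)\n",
              min(x$states[, "circ"]), max(x$states[, "circ"]), x$params$circ0))
  invisible(x)
}

#' CTCAE neutropenia grade of a circulating neutrophil concentration
#'
#' Maps concentrations (10^9 cells/L) to CTCAE grades 0-4 using the standard
#' neutropenia bands. A value exactly at a threshold is assigned the more
#' severe grade. Vectorised over `circ_value`.
#'
#' @param circ_value Circulating concentrations, 10^9 cells/L, >= 0.
#' @param thresholds Decreasing concentration thresholds for grades 1-4.
#' @return Integer vector of grades in `0:4`.
#' @examples
#' grade_neutropenia(c(2, 1.5, 0.9, 0.5, 0.1))
#' @export
grade_neutropenia <- function(circ_value, thresholds = c(1.5, 1.0, 0.5, 0.25)) {
  if (any(!is.finite(circ_value)) || any(circ_value < 0))
    stop("`circ_value` must be finite and >= 0")
  if (length(thresholds) != 4L || is.unsorted(rev(thresholds), strictly = TRUE))
    stop("`thresholds` must be 4 strictly decreasing values")
  vapply(circ_value, function(x) sum(x <= thresholds), integer(1))
}

#' Nadir and recovery summary of a simulated trajectory
#'
#' Two recovery notions are reported, both on the band
#' `circ0 * (1 +/- tolerance_fraction)`. `first_return_time` is the first
#' time at or after the post-dose nadir at which the circulating count
#' re-enters the band — the clinical reading of neutropenia recovery (the
#' count is back at baseline; later rebound overshoot does not count
#' against it). `settling_time` is the first time after the last dose at
#' which the count enters and permanently remains in the band over the
#' simulated horizon — return to the constant basal value, which under
#' damped oscillations can exceed the first return by months. A trajectory
#' with no events has both times 0 by convention.
#'
#' @param traj A [simulate_friberg()] trajectory started at equilibrium.
#' @param tolerance_fraction Half-width of the recovery band as a fraction
#'   of `circ0`.
#' @return A list with `nadir` (10^9 cells/L), `nadir_time` (h),
#'   `nadir_grade` (CTCAE), `first_return_time` (h, `NA` if the count never
#'   re-enters the band), `settling_time` (h, `NA` if the count does not
#'   settle within the horizon), and `settled` (logical).
#' @export
recovery_summary <- function(traj, tolerance_fraction = 0.02) {
  stopifnot(inherits(traj, "friberg_trajectory"))
  circ <- traj$states[, "circ"]
  circ0 <- traj$params$circ0
  ev <- traj$schedule[traj$schedule$kill_fraction > 0, , drop = FALSE]
  if (nrow(ev) == 0L) {
    return(list(nadir = min(circ), nadir_time = traj$times[which.min(circ)],
                nadir_grade = grade_neutropenia(max(min(circ), 0)),
                first_return_time = 0, settling_time = 0, settled = TRUE))
  }
  inside <- abs(circ - circ0) <= tolerance_fraction * circ0
  post <- traj$times >= min(ev$time_h)
  nadir_idx <- which(post)[which.min(circ[post])]
  ret <- which(inside & seq_along(circ) >= nadir_idx)
  first_return <- if (length(ret)) traj$times[ret[1L]] else NA_real_
  cand <- which(traj$times >= max(ev$time_h))
  out_cand <- cand[!inside[cand]]
  if (length(out_cand) == 0L) {
    settling <- max(ev$time_h)  # within band from the last dose onwards
  } else if (max(out_cand) == length(circ)) {
    settling <- NA_real_
  } else {
    settling <- traj$times[max(out_cand) + 1L]
  }
  list(nadir = circ[nadir_idx], nadir_time = traj$times[nadir_idx],
       nadir_grade = grade_neutropenia(max(circ[nadir_idx], 0)),
       first_return_time = first_return,
       settling_time = settling, settled = !is.na(settling))
}

#' Strict local maxima of a series
#'
#' A point is a peak if strictly greater than both grid neighbours; used to
#' characterise damped oscillations of the circulating count.
#'
#' @param x Numeric series on a regular grid.
#' @return Integer indices of the peaks.
#' @export
find_peaks <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  i <- 2:(n - 1L)
  which(x[i] > x[i - 1L] & x[i] > x[i + 1L]) + 1L
}

#' Post-nadir oscillation peaks of the circulating count
#'
#' Returns the times and amplitudes (|peak - circ0|) of strict local maxima
#' of the circulating count occurring after the post-dose nadir. Under
#' damped oscillations (gamma below the Hopf threshold) the amplitude
#' sequence is strictly decreasing.
#'
#' @param traj A [simulate_friberg()] trajectory.
#' @return data.frame with columns `time_h`, `circ`, `amplitude`.
#' @export
oscillation_peaks <- function(traj) {
  stopifnot(inherits(traj, "friberg_trajectory"))
  circ <- traj$states[, "circ"]
  nadir_idx <- which.min(circ)
  pk <- find_peaks(circ)
  pk <- pk[pk > nadir_idx]
  data.frame(time_h = traj$times[pk], circ = circ[pk],
             amplitude = abs(circ[pk] - traj$params$circ0))
}
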