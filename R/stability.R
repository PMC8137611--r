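#' Jacobian of the myelosuppression model at equilibrium
#'
#' Linearization of [friberg_rhs()] at the homeostatic equilibrium. With
#' equal rate constants k the Jacobian is a bidiagonal k-chain with a -k
#' diagonal, except for the proliferating row: its self-term is exactly zero
#' (production and exit cancel at equilibrium) and the feedback contributes
#' a single coupling entry \eqn{-k\gamma} from the circulating pool.
#'
#' @param params A [friberg_params()] object.
#' @return `(n_transit + 2) x (n_transit + 2)` numeric matrix, per-hour units.
#' @export
jacobian_at_equilibrium <- function(params) {
  stopifnot(inherits(params, "friberg_params"))
  n <- params$n_transit
  k <- params$k
  m <- n + 2L
  J <- matrix(0, m, m, dimnames = list(params$state_names, params$state_names))
  J[1L, m] <- -k * params$gamma
  for (i in 2L:m) {
    J[i, i - 1L] <- k
    J[i, i] <- -k
  }
  J
}

#' Eigenvalues of the linearized myelosuppression model
#'
#' Eigenvalues of [jacobian_at_equilibrium()]. In the dimensionless variable
#' \eqn{\mu = \lambda/k} they are the roots of the characteristic relation
#' \eqn{\mu(\mu+1)^{n_{transit}+1} = -\gamma}, so the spectrum scaled by the
#' mean transit time is parameter-free given `gamma` and `n_transit`.
#'
#' @param params A [friberg_params()] object.
#' @return Complex vector of length `n_transit + 2`, sorted by decreasing
#'   real part (ties by decreasing imaginary part), per-hour units.
#' @export
friberg_eigenvalues <- function(params) {
  ev <- eigen(jacobian_at_equilibrium(params), only.values = TRUE)$values
  ev <- as.complex(ev)
  ev[order(-Re(ev), -Im(ev))]
}

max_real_part <- function(params) max(Re(friberg_eigenvalues(params)))

#' Critical feedback exponent of the Hopf bifurcation
#'
#' Smallest `gamma > 0` at which the dominant eigenvalue pair of the
#' linearized model crosses the imaginary axis, located by bracketed
#' root-finding on the maximal real part. The threshold is independent of
#' `circ0` and `mtt`: it admits the closed form
#' \eqn{\omega = \tan(\pi / (2(n_{transit}+1)))},
#' \eqn{\gamma^* = \omega (1+\omega^2)^{(n_{transit}+1)/2}},
#' which for three transit compartments gives 0.568542....
#'
#' @param params A [friberg_params()] object (only `n_transit` matters);
#'   alternatively pass `n_transit` directly.
#' @param n_transit Number of transit compartments, used if `params` is
#'   missing.
#' @param bracket Search interval for `gamma`.
#' @param tol Absolute tolerance on the located `gamma`.
#' @return The critical feedback exponent `gamma*` (dimensionless).
#' @examples
#' hopf_gamma(n_transit = 3)  # ~ 0.5685
#' @export
hopf_gamma <- function(params, n_transit = 3L, bracket = c(1e-3, 10), tol = 1e-10) {
  if (missing(params)) params <- friberg_params(n_transit = n_transit)
  stopifnot(inherits(params, "friberg_params"))
  f <- function(g) {
    p <- friberg_params(circ0 = params$circ0, mtt = params$mtt,
                        gamma = g, n_transit = params$n_transit)
    max_real_part(p)
  }
  lo <- f(bracket[1L]); hi <- f(bracket[2L])
  if (lo >= 0 || hi <= 0)
    stop(sprintf("bracket [%g, %g] does not enclose the stability boundary",
                 bracket[1L], bracket[2L]))
  stats::uniroot(f, interval = bracket, tol = tol)$root
}

#' Closed-form Hopf threshold for the equal-rate transit chain
#'
#' The Hopf condition on \eqn{\mu(\mu+1)^{m+1} = -\gamma} at
#' \eqn{\mu = i\omega} fixes the phase, giving
#' \eqn{\omega = \tan(\pi/(2(m+1)))} and
#' \eqn{\gamma^* = \omega(1+\omega^2)^{(m+1)/2}} with `m = n_transit`.
#' Provided as an analytic cross-check for [hopf_gamma()].
#'
#' @param n_transit Number of transit compartments.
#' @return List with `gamma_star` and the dimensionless Hopf frequency
#'   `omega` (multiply by `k` for per-hour units).
#' @export
hopf_gamma_closed_form <- function(n_transit = 3L) {
  m <- as.integer(n_transit)
  omega <- tan(pi / (2 * (m + 1)))
  list(gamma_star = omega * (1 + omega^2)^((m + 1) / 2), omega = omega)
}

#' Stability classification of the homeostatic equilibrium
#'
#' Classifies the equilibrium by the dominant eigenvalue pair of the
#' linearization: negative real part with a real dominant eigenvalue gives
#' non-oscillatory asymptotic stability; a complex dominant pair gives
#' damped oscillations; a positive real part gives sustained or growing
#' oscillations. Real parts within `tol_marginal` of zero are classified
#' marginal. The `gamma = 0` case carries a zero eigenvalue (the
#' proliferating pool decouples from the feedback) and is flagged
#' degenerate rather than silently classified.
#'
#' @param params A [friberg_params()] object.
#' @param tol_marginal Real-part tolerance (per hour) separating the
#'   exact-Hopf case from numerics.
#' @return Object of class `stability_report`: list with `equilibrium`,
#'   `eigenvalues`, `max_real_part` (per hour), `dominant_freq` (per hour,
#'   |Im| of the dominant pair, 0 for a real dominant eigenvalue),
#'   `classification`, `degenerate`, and the critical exponent `gamma_star`.
#' @examples
#' classify_stability(friberg_params(gamma = 0.5))$classification
#' @export
classify_stability <- function(params, tol_marginal = 1e-9) {
  stopifnot(inherits(params, "friberg_params"))
  ev <- friberg_eigenvalues(params)
  mr <- max(Re(ev))
  dominant <- ev[abs(Re(ev) - mr) <= 1e-12 * max(1, abs(mr))]
  freq <- max(abs(Im(dominant)))
  oscillatory <- freq > tol_marginal
  degenerate <- params$gamma == 0
  classification <- if (abs(mr) <= tol_marginal) {
    if (degenerate) "marginal (degenerate: zero eigenvalue; feedback decoupled)" else "marginal"
  } else if (mr < 0) {
    if (oscillatory) "asymptotically stable (damped oscillations)"
    else "asymptotically stable (non-oscillatory)"
  } else {
    "unstable (sustained/growing oscillations)"
  }
  structure(
    list(equilibrium = steady_state(params), eigenvalues = ev,
         max_real_part = mr, dominant_freq = freq,
         classification = classification, degenerate = degenerate,
         gamma_star = hopf_gamma(params)),
    class = "stability_report"
  )
}

#' @export
print.stability_report <- function(x, ...) {
  cat("Linear stability of the homeostatic equilibrium\n")
  cat(sprintf("  classification : %s\n", x$classification))
  cat(sprintf("  max Re(lambda) : %.6g per h\n", x$max_real_part))
  cat(sprintf("  dominant freq  : %.6g per h\n", x$dominant_freq))
  cat(sprintf("  gamma*         : %.6f\n", x$gamma_star))
  invisible(x)
}

#' Stability scan over the feedback exponent
#'
#' One row per `gamma` value: the maximal real part, the dominant
#' frequency, and the classification. Along the oscillatory branch (where
#' the dominant pair is complex) the maximal real part increases strictly
#' with `gamma`; below the root collision near `gamma = 0.09` the dominant
#' eigenvalue is the decreasing real branch close to `-k * gamma`.
#'
#' @param params A [friberg_params()] object (gamma field ignored).
#' @param gamma_grid Non-negative `gamma` values.
#' @param tol_marginal Passed to the classifier.
#' @return data.frame with columns `gamma`, `max_re_per_h`, `freq_per_h`,
#'   `classification`, `degenerate`.
#' @export
gamma_scan <- function(params, gamma_grid, tol_marginal = 1e-9) {
  stopifnot(inherits(params, "friberg_params"))
  if (any(gamma_grid < 0)) stop("`gamma_grid` values must be >= 0")
  rows <- lapply(gamma_grid, function(g) {
    p <- friberg_params(circ0 = params$circ0, mtt = params$mtt,
                        gamma = g, n_transit = params$n_transit)
    ev <- friberg_eigenvalues(p)
    mr <- max(Re(ev))
    dom <- ev[abs(Re(ev) - mr) <= 1e-12 * max(1, abs(mr))]
    freq <- max(abs(Im(dom)))
    cls <- if (abs(mr) <= tol_marginal) {
      if (g == 0) "marginal (degenerate: zero eigenvalue; feedback decoupled)" else "marginal"
    } else if (mr < 0) {
      if (freq > tol_marginal) "asymptotically stable (damped oscillations)"
      else "asymptotically stable (non-oscillatory)"
    } else "unstable (sustained/growing oscillations)"
    data.frame(gamma = g, max_re_per_h = mr, freq_per_h = freq,
               classification = cls, degenerate = g == 0)
  })
  do.call(rbind, rows)
}
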