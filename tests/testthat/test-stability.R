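test_that("Jacobian matches central finite differences of the RHS", {
  p <- friberg_params(circ0 = 5.05, mtt = 125, gamma = 0.37)
  J <- jacobian_at_equilibrium(p)
  ss <- steady_state(p)
  h <- 1e-6
  Jfd <- matrix(0, length(ss), length(ss))
  for (j in seq_along(ss)) {
    up <- ss; up[j] <- up[j] + h
    dn <- ss; dn[j] <- dn[j] - h
    Jfd[, j] <- (friberg_rhs(up, p) - friberg_rhs(dn, p)) / (2 * h)
  }
  expect_equal(unname(J), Jfd, tolerance = 1e-6)
})

test_that("Jacobian scales inversely with mean transit time", {
  J1 <- jacobian_at_equilibrium(friberg_params(mtt = 125, gamma = 0.3))
  J2 <- jacobian_at_equilibrium(friberg_params(mtt = 250, gamma = 0.3))
  expect_equal(J2, J1 / 2)
})

test_that("gamma = 0 gives the triangular chain spectrum with a zero eigenvalue", {
  p <- friberg_params(gamma = 0, n_transit = 3L)
  J <- jacobian_at_equilibrium(p)
  expect_true(all(J[1L, ] == 0))  # proliferating row decouples
  ev <- friberg_eigenvalues(p)
  expect_spectra_equal(ev, c(0, rep(-p$k, p$n_transit + 1L)), rel_tol = 1e-3)
  expect_lt(abs(ev[1L]), 1e-12)  # the zero eigenvalue is exact
})

test_that("eigenvalues agree with the characteristic-relation roots", {
  set.seed(7)
  for (i in 1:20) {
    gamma <- runif(1, 0.05, 1.2)
    mtt <- runif(1, 20, 200)
    n_transit <- sample(1:6, 1)
    p <- friberg_params(mtt = mtt, gamma = gamma, n_transit = n_transit)
    expect_spectra_equal(friberg_eigenvalues(p),
                         characteristic_eigenvalues(gamma, mtt, n_transit),
                         rel_tol = 1e-8)
  }
})

test_that("real-part sign follows the feedback exponent", {
  expect_lt(max(Re(friberg_eigenvalues(friberg_params(gamma = 0.17)))), 0)
  ev6 <- friberg_eigenvalues(friberg_params(gamma = 0.6))
  dominant <- ev6[which.max(Re(ev6))]
  expect_gt(Re(dominant), 0)
  expect_gt(abs(Im(dominant)), 0)  # crossing pair is complex
})

test_that("Hopf threshold matches the closed form across chain lengths", {
  for (m in 1:8) {
    cf <- hopf_gamma_closed_form(m)
    expect_equal(hopf_gamma(n_transit = m), cf$gamma_star, tolerance = 1e-6)
  }
  # three transit compartments: the canonical 0.5685 value
  expect_equal(round(hopf_gamma(n_transit = 3L), 4), 0.5685)
  expect_equal(hopf_gamma_closed_form(3L)$gamma_star,
               tan(pi / 8) * (1 + tan(pi / 8)^2)^2)
})

test_that("Hopf threshold is invariant to circ0 and mtt rescaling", {
  base <- hopf_gamma(friberg_params(n_transit = 3L))
  expect_equal(hopf_gamma(friberg_params(mtt = 12.5, n_transit = 3L)), base,
               tolerance = 1e-9)
  expect_equal(hopf_gamma(friberg_params(circ0 = 123, mtt = 7, n_transit = 3L)),
               base, tolerance = 1e-9)
})

test_that("stability classification tracks the dominant pair", {
  expect_match(classify_stability(friberg_params(gamma = 0.17))$classification,
               "^asymptotically stable")
  expect_equal(classify_stability(friberg_params(gamma = 0.5))$classification,
               "asymptotically stable (damped oscillations)")
  expect_equal(classify_stability(friberg_params(gamma = 0.7))$classification,
               "unstable (sustained/growing oscillations)")
  r0 <- classify_stability(friberg_params(gamma = 0))
  expect_true(r0$degenerate)
  expect_match(r0$classification, "marginal")
  r <- classify_stability(friberg_params(gamma = 0.3))
  expect_length(r$eigenvalues, 5L)
  expect_equal(r$max_real_part, max(Re(r$eigenvalues)))
})

test_that("gamma scan is monotone and brackets the bifurcation", {
  p <- friberg_params()
  scan <- gamma_scan(p, seq(0, 1, by = 0.02))
  # along the oscillatory branch (complex dominant pair) the maximal real
  # part increases strictly towards and through the crossing; below the
  # root collision (~gamma 0.09) the dominant eigenvalue is the real
  # branch -k*gamma, which decreases
  osc <- scan$freq_per_h > 1e-9
  expect_true(all(diff(scan$max_re_per_h[osc]) > 0))
  expect_true(all(diff(scan$max_re_per_h[!osc & scan$gamma > 0]) < 0))
  expect_true(all(scan$classification[scan$gamma %in% c(0.18, 0.3, 0.5)] ==
                    "asymptotically stable (damped oscillations)"))
  # sign change between 0.56 and 0.58
  expect_lt(scan$max_re_per_h[scan$gamma == 0.56], 0)
  expect_gt(scan$max_re_per_h[scan$gamma == 0.58], 0)
  expect_true(scan$degenerate[scan$gamma == 0])
})

test_that("simulated oscillation period near the bifurcation matches k*omega", {
  p <- friberg_params(gamma = 0.55)
  tr <- simulate_friberg(p, treatment_schedule(0, 0.95), horizon = 5000)
  pk <- oscillation_peaks(tr)
  expect_gte(nrow(pk), 4L)
  omega <- hopf_gamma_closed_form(3L)$omega
  expected_period <- 2 * pi / (p$k * omega)
  expect_equal(mean(diff(pk$time_h)), expected_period,
               tolerance = 0.05)
})
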