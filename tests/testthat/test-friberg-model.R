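test_that("steady state equalizes all compartments and zeroes the derivative", {
  for (case in list(list(circ0 = 5.0, n = 3L), list(circ0 = 1.0, n = 3L),
                    list(circ0 = 2.7, n = 5L))) {
    p <- friberg_params(circ0 = case$circ0, n_transit = case$n)
    ss <- steady_state(p)
    expect_length(ss, case$n + 2L)
    expect_equal(unname(ss), rep(case$circ0, case$n + 2L))
    expect_equal(friberg_rhs(ss, p), rep(0, case$n + 2L))
  }
  expect_error(friberg_params(circ0 = 0), "circ0")
  expect_error(friberg_params(mtt = -1), "mtt")
  expect_error(friberg_params(gamma = -0.1), "gamma")
})

test_that("feedback term drives proliferation when circulating counts fall", {
  p <- friberg_params(circ0 = 5, gamma = 0.3)
  st <- steady_state(p)
  st["circ"] <- p$circ0 / 2
  d <- friberg_rhs(st, p)
  # (circ0/circ)^gamma = 2^gamma > 1: net proliferation positive
  expect_gt(d[1L], 0)
  expect_equal(d[1L], p$k * p$circ0 * (2^p$gamma - 1))

  p0 <- friberg_params(circ0 = 5, gamma = 0)
  for (circ in c(0.5, 2, 9)) {
    st <- steady_state(p0)
    st["circ"] <- circ
    expect_equal(friberg_rhs(st, p0)[1L], 0)  # production and exit cancel
  }
})

test_that("treatment schedules validate, order, and compose simultaneous events", {
  sch <- treatment_schedule(c(504, 0), c(0.5, 0.95))
  expect_equal(sch$time_h, c(0, 504))
  expect_equal(sch$kill_fraction, c(0.95, 0.5))
  expect_error(treatment_schedule(-1, 0.5), ">= 0")
  expect_error(treatment_schedule(0, 1.5), "\\[0, 1\\]")
  # two events at the same time compose through survival fractions
  merged <- treatment_schedule(c(10, 10), c(0.4, 0.5))
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$kill_fraction, 1 - (1 - 0.4) * (1 - 0.5))
})

test_that("event composition algebra holds at the trajectory level", {
  p <- friberg_params(gamma = 0.3)
  two <- simulate_friberg(p, treatment_schedule(c(24, 24), c(0.6, 0.5)),
                          horizon = 400)
  one <- simulate_friberg(p, treatment_schedule(24, 1 - 0.4 * 0.5),
                          horizon = 400)
  expect_equal(two$states, one$states, tolerance = 1e-10)
})

test_that("an empty schedule preserves equilibrium over 10,000 h", {
  p <- friberg_params(gamma = 0.4)
  tr <- simulate_friberg(p, treatment_schedule(), horizon = 10000, dt_out = 10)
  expect_equal(unname(tr$states[1L, ]), rep(p$circ0, p$n_transit + 2L))
  # max deviation below 10x the relative integrator tolerance
  expect_lt(max(abs(tr$states - p$circ0)), 10 * 1e-8 * p$circ0)
})

test_that("gamma = 0 post-kill relaxation matches the linear-chain closed form", {
  p <- friberg_params(circ0 = 5.05, mtt = 125, gamma = 0, n_transit = 3L)
  tr <- simulate_friberg(p, treatment_schedule(0, 0.95), horizon = 1500)
  expected <- linear_chain_circ(tr$times, p$circ0, 0.05 * p$circ0, p$k, p$n_transit)
  expect_equal(unname(tr$states[, "circ"]), expected, tolerance = 1e-7)
  # no feedback: circulating count decays monotonically to the killed level,
  # with no overshoot after its nadir
  circ <- tr$states[, "circ"]
  expect_true(all(diff(circ) <= 1e-10))
})

test_that("states remain non-negative for kill fractions up to 1", {
  p <- friberg_params(gamma = 0.3)
  tr <- suppressWarnings(
    simulate_friberg(p, treatment_schedule(c(0, 100), c(1, 0.5)), horizon = 800))
  expect_true(all(tr$states >= 0))
  # trajectory starts at the supplied (equilibrium) initial condition,
  # modified by the t = 0 kill
  expect_equal(unname(tr$states[1L, "prol"]), 0)
})

test_that("CTCAE grading is monotone with severe-side tie-breaking", {
  expect_equal(grade_neutropenia(c(2.0, 1.6)), c(0L, 0L))
  # values exactly at a threshold take the more severe grade
  expect_equal(grade_neutropenia(c(1.5, 1.0, 0.5, 0.25)), 1:4)
  expect_equal(grade_neutropenia(c(1.2, 0.7, 0.3, 0.1)), 1:4)
  x <- sort(runif(50, 0, 3), decreasing = TRUE)
  expect_true(all(diff(grade_neutropenia(x)) >= 0))
  expect_error(grade_neutropenia(-0.1), ">= 0")
  expect_error(grade_neutropenia(1, thresholds = c(1, 2, 0.5, 0.25)), "decreasing")
})

test_that("a 95% kill under default parameters reaches grade 2 at nadir", {
  p <- friberg_params()
  tr <- simulate_friberg(p, treatment_schedule(0, 0.95), horizon = 720)
  s <- recovery_summary(tr)
  grades <- grade_neutropenia(pmax(tr$states[, "circ"], 0))
  expect_equal(max(grades), 2L)
  expect_equal(s$nadir_grade, 2L)
  expect_equal(s$nadir, min(tr$states[, "circ"]))
})

test_that("recovery summary distinguishes first return from settling", {
  p <- friberg_params(gamma = 0.17)
  # no events: both recovery notions are 0
  quiet <- simulate_friberg(p, treatment_schedule(), horizon = 100)
  s0 <- recovery_summary(quiet)
  expect_equal(s0$first_return_time, 0)
  expect_equal(s0$settling_time, 0)

  tr <- simulate_friberg(p, treatment_schedule(0, 0.95), horizon = 2160)
  s <- recovery_summary(tr, tolerance_fraction = 0.02)
  expect_gt(s$first_return_time, s$nadir_time)
  # rebound overshoot: settling happens after the first return
  expect_gt(s$settling_time, s$first_return_time)
  circ <- tr$states[, "circ"]
  inband <- abs(circ - p$circ0) <= 0.02 * p$circ0
  expect_true(all(inband[tr$times >= s$settling_time]))
})

test_that("damped oscillations have strictly decreasing peak amplitudes", {
  p <- friberg_params(gamma = 0.5)
  tr <- simulate_friberg(p, treatment_schedule(0, 0.95), horizon = 4320)
  pk <- oscillation_peaks(tr)
  expect_gte(nrow(pk), 3L)
  expect_true(all(diff(pk$amplitude) < 0))
})

test_that("peak finder returns strict local maxima only", {
  expect_equal(find_peaks(c(0, 1, 0, 2, 2, 1)), 2L)
  expect_equal(find_peaks(c(1, 2, 3)), integer(0))
  expect_equal(find_peaks(c(0, 3, 1, 4, 0)), c(2L, 4L))
})
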