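test_that("crypt configuration rejects inconsistent bands and times", {
  expect_error(crypt_config(stem_band = c(0, 6), ta_band = c(5, 20)), "below")
  expect_error(crypt_config(ta_band = c(5, 30), n_rows = 30), "within")
  expect_error(crypt_config(cycle_time_mean = 0), "positive")
  expect_error(injury_spec(1.2, c(5, 12)), "\\[0, 1\\]")
  expect_error(injury_spec(0.85, c(12, 5)), "lo, hi")
})

test_that("initialization fills the lattice and localizes proliferation", {
  cfg <- crypt_config(seed = 11)
  st <- init_crypt(cfg)
  expect_equal(sum(st$state != 0L), cfg$n_columns * cfg$n_rows)
  ser <- run_crypt_scenario(cfg, injury = NULL, horizon = 120)
  prof <- colMeans(ser$prolif_profile)
  ta <- (cfg$ta_band[1L]:cfg$ta_band[2L]) + 1L
  above <- (cfg$ta_band[2L] + 2L):cfg$n_rows
  expect_true(all(prof[ta] > 0.5))
  expect_true(all(prof[above] < 0.1))
  # cycling cells form one contiguous low band containing the TA compartment
  cyc_band <- unname(which(prof > 0.5))
  expect_equal(cyc_band, seq_len(max(cyc_band)))
  expect_true(all(ta %in% cyc_band))
})

test_that("runs are deterministic in the seed", {
  cfg <- crypt_config(seed = 23)
  inj <- injury_spec(0.85, c(5, 12))
  a <- run_crypt_scenario(cfg, inj, horizon = 80)
  b <- run_crypt_scenario(cfg, inj, horizon = 80)
  expect_identical(a$villus_count, b$villus_count)
  expect_identical(a$ta_proliferative_count, b$ta_proliferative_count)
  expect_identical(a$prolif_profile, b$prolif_profile)
  c2 <- run_crypt_scenario(crypt_config(seed = 24), inj, horizon = 80)
  expect_false(identical(a$villus_count, c2$villus_count))
})

test_that("time step limit is enforced", {
  st <- init_crypt(crypt_config(seed = 1))
  expect_error(crypt_step(st, dt = 5), "min cycle time")
})

test_that("homeostatic villus balance and exact flux bookkeeping", {
  cfg <- crypt_config(seed = 31)
  ser <- run_crypt_scenario(cfg, injury = NULL, horizon = 240)
  expect_true(all(abs(ser$villus_count - cfg$villus_init) <= 0.1 * cfg$villus_init))
  expect_true(all(ser$crypt_count == cfg$n_columns * cfg$n_rows))
  # cells transferred - cells shed = net villus change, exactly
  expect_equal(ser$transfers_total - ser$shed_total,
               ser$villus_final - cfg$villus_init, tolerance = 1e-9)
})

test_that("a crypt without cycling cells only sheds", {
  st <- init_crypt(crypt_config(seed = 5))
  st$state[st$state %in% c(1L, 2L)] <- 3L  # differentiate everything
  st$clock[] <- NA_real_
  v0 <- st$villus
  for (i in 1:20) st <- crypt_step(st, 0.5)
  expect_equal(st$transfers_total, 0)
  expect_lt(st$villus, v0)
  expect_equal(sum(st$state != 0L), 480L)  # no divisions, no removals
})

test_that("injury arrests the expected share of proliferative cells", {
  cfg <- crypt_config(seed = 41)
  st <- init_crypt(cfg)
  expect_identical(apply_injury(st, injury_spec(0, c(5, 12)))$state, st$state)

  full <- apply_injury(st, injury_spec(1, c(5, 20)))
  rows <- 6:21
  expect_equal(sum(full$state[rows, ] == 2L), 0L)
  expect_equal(sum(full$state[rows, ] == 4L), length(rows) * cfg$n_columns)

  eligible <- sum(st$state[6:13, ] == 2L)
  part <- apply_injury(st, injury_spec(0.85, c(5, 12)))
  hit <- sum(part$state[6:13, ] == 4L)
  # binomial spread: within 5 sd of the expectation
  expect_lt(abs(hit - 0.85 * eligible), 5 * sqrt(eligible * 0.85 * 0.15))
  exact <- apply_injury(st, injury_spec(0.85, c(5, 12), exact = TRUE))
  expect_equal(sum(exact$state[6:13, ] == 4L), round(0.85 * eligible))
})

test_that("arrested cells never divide and never revert", {
  cfg <- crypt_config(seed = 43)
  st <- init_crypt(cfg)
  st <- apply_injury(st, injury_spec(0.85, c(5, 12)))
  n0 <- sum(st$state == 4L)
  for (i in 1:40) st <- crypt_step(st, 0.5)  # 20 h, well before senescence
  # arrest is irreversible: arrested cells persist (none senesce this early),
  # possibly transferring to the villus from the crypt top
  expect_lte(sum(st$state == 4L), n0)
  expect_true(all(is.na(st$clock[st$state == 4L])))
  expect_true(all(st$arrest_age[st$state == 4L] >= 20 - 1e-9))
})

test_that("injury at the low band recovers slower and dents the villus deeper", {
  rec <- list(); nad <- list()
  bands <- list(low = c(5L, 12L), high = c(13L, 20L))
  for (nm in names(bands)) {
    r <- c(); v <- c()
    for (s in 1:3) {
      cfg <- crypt_config(seed = 300 + s + 10 * (nm == "high"))
      ser <- run_crypt_scenario(cfg, injury_spec(0.85, bands[[nm]]), horizon = 264)
      expect_true(all(ser$crypt_count == 480))
      r <- c(r, crypt_recovery_time(ser))
      v <- c(v, villus_nadir(ser)$nadir_fraction)
    }
    rec[[nm]] <- r; nad[[nm]] <- v
  }
  expect_true(all(is.finite(unlist(rec))))
  expect_gt(mean(rec$low), mean(rec$high))
  expect_lt(mean(nad$low), mean(nad$high))
})

test_that("recovery time is zero for a null injury", {
  cfg <- crypt_config(seed = 77)
  ser <- run_crypt_scenario(cfg, injury_spec(0, c(5, 12)), horizon = 120)
  expect_equal(crypt_recovery_time(ser), 0)
})
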