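test_that("sync lag recovers a constructed shift and flags unrelated signals", {
  set.seed(1)
  base <- sin(seq_len(4000) / 15) + rnorm(4000, 0, 0.05)
  expect_equal(as.numeric(sync_lag(base, base, rate_hz = 512)), 0)
  shifted <- c(rep(0, 128), base)[seq_len(4000)]  # delayed by 0.25 s
  lag <- sync_lag(base, shifted, rate_hz = 512)
  expect_lt(abs(as.numeric(lag) - 0.25), 1 / 512 + 1e-9)
  expect_warning(sync_lag(rnorm(2000), rnorm(2000), rate_hz = 512),
                 "below threshold")
})

test_that("run segmentation finds the onset against generator truth", {
  rec <- list(mas_kmh = 15, cas_kmh = 14)
  st <- generate_gait_stream(rec, quiet_truth(), duration_s = 60, seed = 1)
  r <- st[st$side == "R", ]
  imu <- generate_foot_gyro(r, run_start_s = 30, seed = 2)
  # GNSS speed: zero until t = 30, then running speed
  tg <- seq(0, max(imu$time_s), by = 0.1)
  gnss <- data.frame(time_s = tg, speed_ms = ifelse(tg < 30, 0, 3.9))
  win <- segment_run(imu, gnss, duration_s = 60)
  expect_lt(abs(win[["start"]] - 30), 1.5)
  expect_equal(win[["end"]] - win[["start"]], 60)

  quiet <- imu
  quiet$acc_x_g <- 0; quiet$acc_y_g <- 0; quiet$acc_z_g <- 1
  expect_error(segment_run(quiet, gnss), "no sustained run onset")
})

test_that("mid-swing detection counts planted cycles exactly", {
  rec <- list(mas_kmh = 16)
  st <- generate_gait_stream(rec, quiet_truth(), duration_s = 720, seed = 1)
  r <- st[st$side == "R", ]
  expect_equal(nrow(r), 1028)
  imu <- generate_foot_gyro(r, seed = 1)
  ms <- detect_midswings(imu$gyro_y_degs)
  expect_equal(length(ms), 1028)
  expect_length(detect_midswings(rep(0, 10000)), 0)
  # amplitude jitter of +/-20% leaves the count unchanged
  set.seed(3)
  jit <- imu$gyro_y_degs * runif(nrow(imu), 0.8, 1.2)
  expect_equal(length(detect_midswings(jit)), 1028)
})

test_that("temporal parameters recover planted CT/GT within one sample", {
  rec <- list(mas_kmh = 16)
  st <- generate_gait_stream(rec, quiet_truth(), duration_s = 30, seed = 1)
  r <- st[st$side == "R", ]
  imu <- generate_foot_gyro(r, seed = 1)
  ms <- detect_midswings(imu$gyro_y_degs)
  tp <- temporal_parameters(imu, ms)
  one_sample_ms <- 1000 / 512
  expect_lt(max(abs(tp$ct_ms - 250)), 2 * one_sample_ms)
  expect_lt(max(abs(tp$gt_ms - 700)), one_sample_ms + 1e-9)
  expect_equal(tp$st_ms, tp$gt_ms - tp$ct_ms)
  expect_equal(attr(tp, "n_invalid"), 0L)
  # a cycle without any stationary phase is flagged and excluded
  imu2 <- imu
  dec <- attr(imu, "planted")
  mask <- imu2$time_s >= dec$stance_on[3] & imu2$time_s < dec$stance_off[3]
  imu2$gyro_y_degs[mask] <- 200
  tp2 <- temporal_parameters(imu2, ms)
  expect_equal(attr(tp2, "n_invalid"), 1L)
  expect_equal(nrow(tp2), nrow(tp) - 1)
})

test_that("duty factor is the CT/GT percentage", {
  expect_equal(duty_factor(700, 700), 100)
  expect_equal(duty_factor(250, 700), 250 / 700 * 100)
  expect_equal(duty_factor(0, 700), 0)
  expect_error(duty_factor(250, 0), "gt_ms")
})

test_that("vertical stiffness matches the sine-force ODE oracle to < 0.5%", {
  grid <- expand.grid(tc = seq(0.15, 0.35, by = 0.05),
                      tf = seq(0, 0.2, by = 0.05),
                      m = c(50, 70, 90))
  closed <- vertical_stiffness(grid$tc, grid$tf, grid$m)
  oracle <- mapply(vs_ode_oracle, grid$tc, grid$tf, grid$m)
  expect_true(all(abs(closed - oracle) / oracle < 0.005))
  # t_f = 0 limit: F_max = m g pi / 2 exactly
  fmax0 <- 70 * 9.81 * pi / 2
  dz0 <- fmax0 * 0.25^2 / (70 * pi^2) - 9.81 * 0.25^2 / 8
  expect_equal(vertical_stiffness(0.25, 0, 70), fmax0 / dz0 / 1000)
  # doubling mass doubles F_max; the closed form tracks the oracle
  expect_equal(vertical_stiffness(0.2, 0.12, 140),
               vs_ode_oracle(0.2, 0.12, 140), tolerance = 0.005)
  expect_error(vertical_stiffness(0, 0.1, 70), "ct_s")
  expect_error(vertical_stiffness(0.2, 0.1, -1), "mass")
})

test_that("VS is monotonically decreasing in contact time", {
  tcs <- seq(0.16, 0.34, by = 0.02)
  vs <- vertical_stiffness(tcs, 0.12, 70)
  expect_true(all(diff(vs) < 0))
})

test_that("symmetry index matches its closed form and invariances", {
  expect_equal(symmetry_index(250, 250), 0)
  expect_equal(symmetry_index(110, 90), 20)
  expect_equal(symmetry_index(10, 0), 200)
  expect_error(symmetry_index(0, 0), "positive")
  # symmetric under exchange, scale-invariant, bounded
  set.seed(5)
  xl <- runif(200, 1, 100); xr <- runif(200, 1, 100)
  si <- symmetry_index(xl, xr)
  expect_equal(si, symmetry_index(xr, xl))
  expect_equal(si, symmetry_index(3.7 * xl, 3.7 * xr))
  expect_true(all(si >= 0 & si <= 200))
  expect_true(all((si == 0) == (xl == xr)))
})

test_that("cycle pairing builds symmetry series and validity checks", {
  rec <- list(mas_kmh = 16)
  st <- generate_gait_stream(rec, quiet_truth(), duration_s = 120, seed = 1)
  ser <- cycle_series_from_stream(st, mass_kg = 70)
  expect_true(ser$valid)
  expect_equal(ser$n_unpaired, 0L)
  expect_true(all(ser$symmetry$ct_si == 0))
  expect_true(all(ser$symmetry$gt_si == 0))

  # +10% left CT offset: SI = 2 * 0.1 / 2.1 * 100
  l <- st[st$side == "L", ]; r <- st[st$side == "R", ]
  l$ct_ms <- l$ct_ms * 1.1
  ser2 <- build_cycle_series(l, r, mass_kg = 70)
  expect_equal(unique(round(ser2$symmetry$ct_si, 6)),
               round(2 * 0.1 / 2.1 * 100, 6))

  # a missing left cycle leaves one right cycle unpaired
  ser3 <- build_cycle_series(l[-5, ], r, mass_kg = 70)
  expect_equal(ser3$n_unpaired, 1L)
  expect_equal(nrow(ser3$symmetry), nrow(r) - 1)
})
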