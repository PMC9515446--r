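make_trace <- function(speed, dt = 0.1) {
  n <- length(speed)
  structure(data.frame(time_s = (seq_len(n) - 1) * dt,
                       lat_deg = 0, lon_deg = 0, speed_ms = speed),
            class = c("gnss_trace", "data.frame"))
}

test_that("speed outlier filter replaces isolated spikes and nothing else", {
  # constant 4 m/s with one spike: the spike is the only flagged sample
  v <- rep(4, 1200)
  v[600] <- 7
  tr <- remove_speed_outliers(make_trace(v))
  expect_equal(attr(tr, "n_replaced"), 1)
  expect_equal(tr$speed_ms, rep(4, 1200))

  # constant signal (sd = 0): untouched
  tc <- remove_speed_outliers(make_trace(rep(4, 1200)))
  expect_equal(tc$speed_ms, rep(4, 1200))
  expect_equal(attr(tc, "n_replaced"), 0)

  # spike at the first sample: nearest-retained extrapolation
  v2 <- rep(4, 1200)
  v2[1] <- 30
  t2 <- remove_speed_outliers(make_trace(v2))
  expect_equal(t2$speed_ms, rep(4, 1200))

  # noisy signal: the spike is removed, the bulk of samples untouched
  set.seed(13)
  v3 <- rep(4, 1200) + rnorm(1200, 0, 0.05)
  v3[600] <- v3[600] + 3
  t3 <- remove_speed_outliers(make_trace(v3))
  expect_lt(abs(t3$speed_ms[600] - 4), 0.2)
  expect_lt(attr(t3, "n_replaced") / 1200, 0.06)  # ~ the 2-sd tail mass

  expect_error(remove_speed_outliers(make_trace(rep(4, 100)), window_s = 60),
               "shorter")
})

test_that("outlier filter is idempotent once spikes are removed", {
  v <- rep(4, 2000)
  v[c(300, 900, 1500)] <- c(8, 9, 7.5)
  once <- remove_speed_outliers(make_trace(v))
  twice <- remove_speed_outliers(once)
  expect_equal(twice$speed_ms, once$speed_ms, tolerance = 1e-12)
  expect_equal(attr(twice, "n_replaced"), 0)
})

test_that("haversine distance matches the arc-length oracle and is symmetric", {
  expect_equal(haversine_m(10, 20, 10, 20), 0)
  # 0.001 degrees of latitude = pi * R / 180 * 0.001
  oracle <- pi * 6371000 / 180 * 0.001
  expect_equal(haversine_m(0, 0, 0.001, 0), oracle, tolerance = 1e-5)
  expect_identical(haversine_m(46.5, 6.6, 46.51, 6.62),
                   haversine_m(46.51, 6.62, 46.5, 6.6))
})

test_that("strapdown and coordinate distances behave on elementary inputs", {
  tr <- make_trace(rep(4, 601))  # 60 s at 4 m/s
  expect_equal(distance_strapdown(tr), 240)
  expect_equal(distance_strapdown(make_trace(rep(0, 100))), 0)
  expect_equal(distance_coordinates(make_trace(rep(0, 100))), 0)
  expect_error(distance_strapdown(make_trace(4)), "short")
})

test_that("position noise inflates the coordinate polyline", {
  rec <- const_speed_record(4.2)
  d0 <- distance_coordinates(clean_trace(4.2))
  set.seed(7)
  inflated <- vapply(1:5, function(s) {
    tr <- generate_track_trajectory(rec, noise = noise_spec(speed_sd = 0,
                                                            outlier_rate = 0),
                                    decay_frac = 0, start_ramp = 1,
                                    end_kick = 0, seed = s)
    distance_coordinates(tr)
  }, numeric(1))
  expect_true(all(inflated > d0))
})

test_that("lap peak detection recovers planted lap structure", {
  tr <- clean_trace(4.2)
  truth <- attr(tr, "truth")
  dec <- detect_lap_peaks(tr$lat_deg)
  # planted apex crossings are the oracle
  expect_equal(dec$n_p, length(truth$peak_times_s))
  got <- tr$time_s[dec$peak_indices]
  expect_lt(max(abs(got - truth$peak_times_s)), 1.5)

  expect_error(detect_lap_peaks(rep(46.5, 1000)), "no lap structure")

  # pure sinusoid: one cycle per lap, d_a = samples per lap within one sample
  lat <- sin(2 * pi * seq(0, 10, length.out = 6001))  # 10 laps, 600/lap
  dec2 <- detect_lap_peaks(lat, rate_hz = 10, min_lap_time_s = 30)
  expect_equal(dec2$d_a, 600, tolerance = 1 / 600)
})

test_that("lap-count distance follows the peak-count formula", {
  dec <- structure(list(peak_indices = c(1000, 7000), n_p = 8, d_a = 6000,
                        l_s = 3000), class = "lap_decomposition")
  expect_equal(distance_lap_count(dec), 7 * 400 + 3000 / 6000 * 400)
  dec0 <- structure(list(peak_indices = 1:11, n_p = 11, d_a = 500, l_s = 0),
                    class = "lap_decomposition")
  expect_equal(distance_lap_count(dec0), 4000)
  expect_equal(distance_lap_count(dec, lap_length_m = 407),
               distance_lap_count(dec) * 407 / 400)
  dec$d_a <- 0
  expect_error(distance_lap_count(dec), "d_a")
})

test_that("lap-count distance is invariant to uniform resampling", {
  tr <- clean_trace(4.2)
  dec1 <- detect_lap_peaks(tr$lat_deg, rate_hz = 10)
  half <- tr$lat_deg[seq(1, nrow(tr), by = 2)]
  dec2 <- detect_lap_peaks(half, rate_hz = 5)
  expect_equal(distance_lap_count(dec1), distance_lap_count(dec2),
               tolerance = 0.002)
})

test_that("all five estimators agree with truth on noise-free runs", {
  tr <- clean_trace(4.2)
  est <- estimate_distances(tr)
  expect_true(all(abs(est - 3024) / 3024 < 0.005))
  # hybrids reduce to whole laps when partial segments carry no distance
  dec <- detect_lap_peaks(tr$lat_deg)
  still <- tr
  pre <- seq_len(dec$peak_indices[1])
  post <- dec$peak_indices[dec$n_p]:nrow(tr)
  still$speed_ms[c(pre, post)] <- 0
  still$lat_deg[pre] <- still$lat_deg[dec$peak_indices[1]]
  still$lon_deg[pre] <- still$lon_deg[dec$peak_indices[1]]
  still$lat_deg[post] <- still$lat_deg[dec$peak_indices[dec$n_p]]
  still$lon_deg[post] <- still$lon_deg[dec$peak_indices[dec$n_p]]
  expect_equal(distance_lap_strapdown(still, dec), (dec$n_p - 1) * 400)
  expect_equal(distance_lap_coordinates(still, dec), (dec$n_p - 1) * 400)
})

test_that("method comparison reproduces a hand-computed error table", {
  est <- cbind(A = c(2990, 3010, 3000), B = c(2980, 2980, 2980))
  ref <- c(3000, 3000, 3000)
  rep <- compare_methods(est, ref)
  a <- rep[rep$method == "A", ]
  expect_equal(a$mae_m, mean(abs(c(-10, 10, 0))))
  expect_equal(a$bias_m, 0)
  d <- c(-10, 10, 0)
  expect_equal(a$loa_upper_m, mean(d) + 1.96 * sd(d))
  p <- d / 3000 * 100
  expect_equal(a$median_err_pct, median(p))
  expect_equal(a$iqr_err_pct, unname(diff(quantile(p, c(.25, .75)))))
  b <- rep[rep$method == "B", ]
  expect_equal(b$bias_m, -20)
  expect_equal(b$mae_m, 20)
  expect_equal(b$loa_upper_m - b$loa_lower_m, 0)
  # identical estimates: zeros everywhere
  z <- compare_methods(cbind(Z = ref), ref)
  expect_equal(z$mae_m, 0)
  expect_equal(z$loa_upper_m, 0)
})
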