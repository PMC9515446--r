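#' Geometry of a stadium running track
#'
#' A standard athletics oval: two parallel straights joined by two
#' semicircular curves. The straights are oriented north-south so the
#' latitude of a runner shows exactly one smooth peak per lap (at the apex of
#' the northern curve), which is what the lap-counting distance estimators
#' rely on. The default dimensions reproduce a 400 m track (straights of
#' 84.39 m, curve radius ~36.8 m); a positive `lane_offset` widens the curves
#' as running in an outer lane does, lengthening the lap.
#'
#' @param lap_length Nominal lap length in metres (lane 1).
#' @param straight_length Length of each straight (m).
#' @param curve_radius Curve radius (m); derived from `lap_length` and
#'   `straight_length` when `NULL`.
#' @param origin_lat,origin_lon Geographic position of the track origin
#'   (degrees, WGS84); metres are mapped to degrees by a local tangent plane
#'   at this point.
#' @param lane_offset Extra curve radius for outer lanes (m).
#' @return An object of class `track_geometry` with the effective lap length
#'   in `$lap_length`.
#' @export
track_geometry <- function(lap_length = 400,
                           straight_length = 84.39,
                           curve_radius = NULL,
                           origin_lat = 46.52,
                           origin_lon = 6.62,
                           lane_offset = 0) {
  if (lap_length <= 0) stop("`lap_length` must be positive", call. = FALSE)
  if (is.null(curve_radius))
    curve_radius <- (lap_length - 2 * straight_length) / (2 * pi)
  closure <- 2 * straight_length + 2 * pi * curve_radius
  if (abs(closure - lap_length) > 0.5)
    stop(sprintf(
      "track does not close: 2*straight + 2*pi*radius = %.2f m but lap_length = %.2f m",
      closure, lap_length), call. = FALSE)
  r_eff <- curve_radius + lane_offset
  structure(
    list(lap_length = 2 * straight_length + 2 * pi * r_eff,
         straight_length = straight_length,
         curve_radius = r_eff,
         origin_lat = origin_lat, origin_lon = origin_lon,
         lane_offset = lane_offset),
    class = "track_geometry"
  )
}

#' GNSS noise specification
#'
#' Noise model for simulated GNSS traces. Speed noise is independent Gaussian
#' per sample; position noise is first-order autocorrelated Gaussian per axis
#' (GNSS drift is correlated in time). Isolated speed spikes of `outlier_k`
#' standard deviations are injected at rate `outlier_rate`, sized to be
#' unambiguously removable by the 2-SD sliding-window filter.
#'
#' Two per-participant terms let a simulated cohort reproduce the large
#' between-runner spread of integration-based distance estimates that field
#' recordings show (receiver drift differs from runner to runner):
#' `speed_bias_mean`/`speed_bias_sd` draw one multiplicative ground-speed bias
#' per trace, and `pos_sd_jitter` draws the positional sd per trace from
#' `U(pos_sd - jitter, pos_sd + jitter)`. Both default to zero; the
#' [noise_preset()] `"field"` turns them on.
#'
#' @param pos_sd Stationary positional noise sd per axis (m).
#' @param pos_phi AR(1) coefficient of positional noise per second (the
#'   per-sample coefficient is `pos_phi^(1/rate)`); 0.95 gives a drift
#'   correlation time of about 20 s, consistent with slowly wandering GNSS
#'   fixes rather than sample-to-sample jitter.
#' @param speed_sd Ground-speed noise sd (m/s).
#' @param speed_bias_mean,speed_bias_sd Per-trace multiplicative speed bias:
#'   the trace speed is scaled by `1 + mean + N(0, sd)`.
#' @param pos_sd_jitter Half-width of the per-trace uniform draw around
#'   `pos_sd` (m).
#' @param outlier_rate Fraction of speed samples replaced by spikes.
#' @param outlier_k Spike magnitude in units of `speed_sd`.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(pos_sd = 1.5, pos_phi = 0.95,
                       speed_sd = 0.15,
                       speed_bias_mean = 0, speed_bias_sd = 0,
                       pos_sd_jitter = 0,
                       outlier_rate = 0.002, outlier_k = 6) {
  if (pos_sd < 0 || speed_sd < 0 || outlier_rate < 0 || outlier_rate > 1)
    stop("invalid noise specification", call. = FALSE)
  if (pos_phi < 0 || pos_phi >= 1)
    stop("`pos_phi` must lie in [0, 1)", call. = FALSE)
  structure(
    list(pos_sd = pos_sd, pos_phi = pos_phi, speed_sd = speed_sd,
         speed_bias_mean = speed_bias_mean, speed_bias_sd = speed_bias_sd,
         pos_sd_jitter = pos_sd_jitter,
         outlier_rate = outlier_rate, outlier_k = outlier_k),
    class = "noise_spec"
  )
}

#' Named noise presets
#'
#' `"none"` disables every noise source (ground-truth traces); `"default"`
#' is the plain white-speed / AR-position model; `"field"` adds the
#' per-participant speed bias and positional-sd spread that make a simulated
#' cohort's distance-error distribution resemble field recordings.
#'
#' @param name One of `"none"`, `"default"`, `"field"`.
#' @return A [noise_spec()].
#' @export
noise_preset <- function(name = c("none", "default", "field")) {
  switch(match.arg(name),
    none = noise_spec(pos_sd = 0, speed_sd = 0, outlier_rate = 0),
    default = noise_spec(),
    field = noise_spec(speed_bias_mean = -0.02, speed_bias_sd = 0.03,
                       pos_sd_jitter = 1.0)
  )
}

# Map arc-length positions (m, measured anticlockwise from the south-west
# corner heading north) onto stadium x/y coordinates (m).
stadium_xy <- function(s, geom) {
  Ls <- geom$straight_length
  r <- geom$curve_radius
  lap <- geom$lap_length
  s <- s %% lap
  x <- numeric(length(s)); y <- numeric(length(s))
  seg1 <- s < Ls
  x[seg1] <- 0; y[seg1] <- s[seg1]
  seg2 <- s >= Ls & s < Ls + pi * r
  th <- (s[seg2] - Ls) / r
  x[seg2] <- r - r * cos(th); y[seg2] <- Ls + r * sin(th)
  seg3 <- s >= Ls + pi * r & s < 2 * Ls + pi * r
  x[seg3] <- 2 * r; y[seg3] <- Ls - (s[seg3] - Ls - pi * r)
  seg4 <- s >= 2 * Ls + pi * r
  th <- (s[seg4] - 2 * Ls - pi * r) / r
  x[seg4] <- r + r * cos(th); y[seg4] <- -r * sin(th)
  cbind(x = x, y = y)
}

# Local tangent-plane (equirectangular) mapping metres -> degrees at the
# track origin; adequate over a 400 m extent (Haversine inversion agrees to
# well under 0.01%).
xy_to_latlon <- function(xy, geom) {
  lat <- geom$origin_lat + xy[, "y"] / M_PER_DEG_LAT
  lon <- geom$origin_lon +
    xy[, "x"] / (M_PER_DEG_LAT * cos(geom$origin_lat * pi / 180))
  cbind(lat = lat, lon = lon)
}

#' Simulate a 12-minute GNSS trace on an oval track
#'
#' Generates a 10 Hz chest-GNSS recording of one participant's Cooper test:
#' positions follow the stadium oval at the participant's Cooper average
#' speed (CAS), with an optional qualitative pacing shape (fast first minute,
#' slow linear decay through minute 11, end spurt), then positional/speed
#' noise and isolated speed outliers are applied per `noise`.
#'
#' @param record One row of a [generate_cohort()] table (needs `cas_kmh`), or
#'   a list with `cas_kmh`.
#' @param geom A [track_geometry()].
#' @param noise A [noise_spec()].
#' @param duration_s Test duration (s).
#' @param rate_hz Sampling rate (Hz); must be positive.
#' @param decay_frac Relative speed drop from minute 1 to minute 11
#'   (0 = constant pace).
#' @param start_ramp Relative speed at t = 0 (fraction of the minute-1
#'   speed); 1 = no initial ramp.
#' @param end_kick Relative speed increase over the final minute.
#' @param start_offset_m Arc-length position on the track at t = 0 (m).
#' @param seed Integer seed.
#'
#' @return A data frame of class `gnss_trace` with columns `time_s`,
#'   `lat_deg`, `lon_deg`, `speed_ms` and an attribute `truth`: a list with
#'   the ground-truth covered distance (`distance_m`), completed laps
#'   (`n_laps`), noise-free speed (`speed_true_ms`), the times at which the
#'   runner crosses the northern apex (`peak_times_s`), and the per-trace
#'   noise draws actually used.
#' @export
generate_track_trajectory <- function(record,
                                      geom = track_geometry(),
                                      noise = noise_preset("default"),
                                      duration_s = 720,
                                      rate_hz = 10,
                                      decay_frac = 0.08,
                                      start_ramp = 0.9,
                                      end_kick = 0.05,
                                      start_offset_m = 0,
                                      seed = 1L) {
  if (rate_hz <= 0) stop("`rate_hz` must be positive", call. = FALSE)
  stopifnot(inherits(geom, "track_geometry"), inherits(noise, "noise_spec"))
  cas_ms <- record$cas_kmh / 3.6
  if (!is.finite(cas_ms) || cas_ms <= 0)
    stop("participant record must carry a positive `cas_kmh`", call. = FALSE)

  time_s <- seq(0, duration_s, by = 1 / rate_hz)
  n <- length(time_s)

  # Pacing shape: ramp over minute 0-1, linear decay to minute 11, end kick;
  # normalised to unit mean so the mean speed equals CAS.
  shape <- rep(1, n)
  t1 <- pmin(duration_s, 60); t2 <- max(t1, duration_s - 60)
  v_start <- 1 + decay_frac / 2
  v_end <- 1 - decay_frac / 2
  mid <- time_s >= t1 & time_s < t2
  shape[mid] <- v_start + (v_end - v_start) * (time_s[mid] - t1) / (t2 - t1)
  first <- time_s < t1
  shape[first] <- start_ramp * v_start +
    (1 - start_ramp) * v_start * time_s[first] / t1
  if (duration_s > t2) {
    last <- time_s >= t2
    shape[last] <- v_end + end_kick * (time_s[last] - t2) / (duration_s - t2)
  }
  shape <- shape / mean(shape)
  speed_true <- cas_ms * shape

  out <- withr_seed(seed, {
    # Arc length along the oval (trapezoidal integral of true speed).
    s_along <- start_offset_m + cumtrapz_num(time_s, speed_true)
    xy <- stadium_xy(s_along, geom)

    pos_sd <- noise$pos_sd
    if (noise$pos_sd_jitter > 0)
      pos_sd <- max(0, runif(1, pos_sd - noise$pos_sd_jitter,
                             pos_sd + noise$pos_sd_jitter))
    if (pos_sd > 0) {
      phi <- noise$pos_phi^(1 / rate_hz)  # per-second coefficient -> per sample
      innov_sd <- pos_sd * sqrt(1 - phi^2)
      ex <- as.numeric(stats::arima.sim(list(ar = phi), n, sd = innov_sd))
      ey <- as.numeric(stats::arima.sim(list(ar = phi), n, sd = innov_sd))
      xy[, "x"] <- xy[, "x"] + ex
      xy[, "y"] <- xy[, "y"] + ey
    }
    ll <- xy_to_latlon(xy, geom)

    bias_mult <- 1 + noise$speed_bias_mean +
      (if (noise$speed_bias_sd > 0) rnorm(1, 0, noise$speed_bias_sd) else 0)
    speed_obs <- speed_true * bias_mult
    if (noise$speed_sd > 0) speed_obs <- speed_obs + rnorm(n, 0, noise$speed_sd)
    n_out <- 0L
    if (noise$outlier_rate > 0 && noise$speed_sd > 0) {
      idx <- which(runif(n) < noise$outlier_rate)
      # keep spikes isolated
      idx <- idx[c(TRUE, diff(idx) > 1)]
      speed_obs[idx] <- speed_obs[idx] + noise$outlier_k * noise$speed_sd
      n_out <- length(idx)
    }
    speed_obs <- pmax(speed_obs, 0)

    total_m <- s_along[n] - start_offset_m
    # Times at which the runner crosses the northern apex (latitude peak).
    apex0 <- geom$straight_length + (pi / 2) * geom$curve_radius
    apexes <- seq(apex0, by = geom$lap_length,
                  length.out = ceiling((start_offset_m + total_m) /
                                         geom$lap_length) + 1)
    apexes <- apexes[apexes > s_along[1] & apexes <= s_along[n]]
    peak_times <- approx(s_along, time_s, xout = apexes)$y

    trace <- data.frame(time_s = time_s,
                        lat_deg = ll[, "lat"], lon_deg = ll[, "lon"],
                        speed_ms = speed_obs)
    attr(trace, "truth") <- list(
      distance_m = total_m,
      n_laps = floor(total_m / geom$lap_length),
      speed_true_ms = speed_true,
      peak_times_s = peak_times,
      pos_sd_used = pos_sd,
      speed_bias_mult = bias_mult,
      n_outliers = n_out,
      lap_length_m = geom$lap_length
    )
    class(trace) <- c("gnss_trace", "data.frame")
    trace
  })
  out
}

# Cumulative trapezoidal integral of y over x, same length as x (starts at 0).
cumtrapz_num <- function(x, y) {
  n <- length(x)
  c(0, cumsum((y[-1] + y[-n]) / 2 * diff(x)))
}
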