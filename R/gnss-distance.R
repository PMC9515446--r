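#' Remove ground-speed outliers with a sliding-window 2-SD filter
#'
#' Flags speed samples lying more than `k_sd` standard deviations from the
#' mean of a centred sliding window and replaces them with values linearly
#' interpolated between the nearest retained neighbours. Windows are
#' truncated at the trace boundaries; flagged samples at the very edges take
#' the nearest retained value (pure extrapolation).
#'
#' @param trace A `gnss_trace` data frame (`time_s`, `speed_ms`, ...).
#' @param window_s Sliding-window width (s).
#' @param k_sd Rejection threshold in window standard deviations.
#' @return The trace with outlying `speed_ms` samples replaced; the number of
#'   replaced samples is attached as attribute `n_replaced`.
#' @export
remove_speed_outliers <- function(trace, window_s = 60, k_sd = 2) {
  check_gnss(trace)
  t <- trace$time_s
  v <- trace$speed_ms
  n <- length(v)
  if (window_s >= (t[n] - t[1]))
    stop("`window_s` must be shorter than the trace duration", call. = FALSE)
  dt <- median(diff(t))
  half <- max(1L, floor(window_s / dt / 2))
  # centred rolling mean / sd via cumulative sums (windows truncated at the
  # boundaries)
  cs <- cumsum(c(0, v)); cs2 <- cumsum(c(0, v^2))
  lo <- pmax(1L, seq_len(n) - half); hi <- pmin(n, seq_len(n) + half)
  cnt <- hi - lo + 1
  mu <- (cs[hi + 1] - cs[lo]) / cnt
  ss <- (cs2[hi + 1] - cs2[lo]) - cnt * mu^2
  sdw <- sqrt(pmax(ss, 0) / pmax(cnt - 1, 1))
  bad <- abs(v - mu) > k_sd * sdw & sdw > 0
  if (any(bad)) {
    keep <- which(!bad)
    if (length(keep) < 2)
      stop("outlier filter rejected nearly all samples", call. = FALSE)
    v[bad] <- approx(t[keep], v[keep], xout = t[bad], rule = 2)$y
    trace$speed_ms <- v
  }
  attr(trace, "n_replaced") <- sum(bad)
  trace
}

#' Great-circle distance (Haversine)
#'
#' Haversine distance between coordinate pairs on a sphere of radius
#' `radius_m`. Vectorised; symmetric in its arguments.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in degrees.
#' @param radius_m Earth radius (m).
#' @return Distance(s) in metres.
#' @export
haversine_m <- function(lat1, lon1, lat2, lon2, radius_m = EARTH_RADIUS_M) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = radius_m)
}

#' Total distance by strapdown integration of ground speed
#'
#' Trapezoidal time-integral of the (preprocessed) GNSS ground speed.
#'
#' @param trace A `gnss_trace` data frame.
#' @return Distance in metres.
#' @export
distance_strapdown <- function(trace) {
  check_gnss(trace)
  if (nrow(trace) < 2) stop("trace too short to integrate", call. = FALSE)
  pracma::trapz(trace$time_s, trace$speed_ms)
}

#' Total distance by coordinate summation
#'
#' Sum of Haversine distances over consecutive GNSS fixes.
#'
#' @inheritParams distance_strapdown
#' @param radius_m Earth radius (m).
#' @return Distance in metres.
#' @export
distance_coordinates <- function(trace, radius_m = EARTH_RADIUS_M) {
  check_gnss(trace)
  n <- nrow(trace)
  if (n < 2) stop("trace too short", call. = FALSE)
  sum(haversine_m(trace$lat_deg[-n], trace$lon_deg[-n],
                  trace$lat_deg[-1], trace$lon_deg[-1], radius_m))
}

#' Detect lap peaks in the latitude signal
#'
#' On an oval track the latitude of the runner oscillates once per lap; the
#' number of latitude peaks counts laps. Peaks must rise above the signal
#' mid-line (half the amplitude) and be separated by at least `min_lap_time_s`.
#' The signal is lightly smoothed with a centred moving average before
#' detection so positional noise does not split a peak.
#'
#' @param lat_series Latitude samples (degrees or any monotone transform).
#' @param rate_hz Sampling rate (Hz).
#' @param min_lap_time_s Minimum plausible lap duration (s).
#' @param prominence_frac Minimum peak height above the minimum, as a
#'   fraction of the full amplitude.
#' @param smooth_s Moving-average window for pre-smoothing (s); 0 disables.
#' @return An object of class `lap_decomposition`: list with `peak_indices`,
#'   `n_p`, `d_a` (mean inter-peak spacing, samples) and `l_s` (samples
#'   outside the first-to-last-peak span).
#' @export
detect_lap_peaks <- function(lat_series, rate_hz = 10, min_lap_time_s = 50,
                             prominence_frac = 0.5, smooth_s = 2) {
  x <- as.numeric(lat_series)
  n <- length(x)
  if (n < 3 || max(x) == min(x))
    stop("latitude signal carries no lap structure", call. = FALSE)
  if (smooth_s > 0) {
    w <- max(1L, round(smooth_s * rate_hz))
    if (w %% 2 == 0) w <- w + 1L
    xs <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
    # fill the filter's edge NAs with the raw signal
    xs[is.na(xs)] <- x[is.na(xs)]
  } else xs <- x
  amp <- max(xs) - min(xs)
  height <- min(xs) + prominence_frac * amp
  pk <- pracma::findpeaks(xs, minpeakheight = height,
                          minpeakdistance = max(1L, round(min_lap_time_s * rate_hz)),
                          sortstr = FALSE)
  if (is.null(pk) || nrow(pk) < 2)
    stop("fewer than two latitude peaks: lap methods unavailable",
         call. = FALSE)
  idx <- sort(pk[, 2])
  structure(
    list(peak_indices = idx,
         n_p = length(idx),
         d_a = mean(diff(idx)),
         l_s = (idx[1] - 1) + (n - idx[length(idx)])),
    class = "lap_decomposition"
  )
}

#' Distance by lap counting
#'
#' With `n_p` latitude peaks, `d_a` the mean inter-peak spacing and `l_s` the
#' signal length outside the peak-to-peak span, the covered distance is
#' `(n_p - 1) * lap + l_s / d_a * lap`.
#'
#' @param dec A [detect_lap_peaks()] decomposition.
#' @param lap_length_m Lap length (m); update for outer lanes.
#' @return Distance in metres.
#' @export
distance_lap_count <- function(dec, lap_length_m = 400) {
  stopifnot(inherits(dec, "lap_decomposition"))
  if (dec$d_a <= 0) stop("degenerate lap decomposition (d_a = 0)", call. = FALSE)
  (dec$n_p - 1) * lap_length_m + dec$l_s / dec$d_a * lap_length_m
}

# Shared partial-segment logic for the two lap-counting hybrids: full laps
# between the first and last peak, plus the distance covered before the first
# and after the last peak measured by `partial_fun`.
lap_hybrid <- function(trace, dec, lap_length_m, partial_fun) {
  stopifnot(inherits(dec, "lap_decomposition"))
  n <- nrow(trace)
  i1 <- dec$peak_indices[1]
  i2 <- dec$peak_indices[dec$n_p]
  d <- (dec$n_p - 1) * lap_length_m
  if (i1 > 1) d <- d + partial_fun(trace[seq_len(i1), , drop = FALSE])
  if (i2 < n) d <- d + partial_fun(trace[i2:n, , drop = FALSE])
  d
}

#' Distance by lap counting plus strapdown integration of partial laps
#'
#' @param trace A preprocessed `gnss_trace`.
#' @param dec A [detect_lap_peaks()] decomposition of its latitude signal.
#' @param lap_length_m Lap length (m).
#' @return Distance in metres.
#' @export
distance_lap_strapdown <- function(trace, dec, lap_length_m = 400) {
  check_gnss(trace)
  lap_hybrid(trace, dec, lap_length_m, distance_strapdown)
}

#' Distance by lap counting plus coordinate summation of partial laps
#'
#' @inheritParams distance_lap_strapdown
#' @return Distance in metres.
#' @export
distance_lap_coordinates <- function(trace, dec, lap_length_m = 400) {
  check_gnss(trace)
  lap_hybrid(trace, dec, lap_length_m, distance_coordinates)
}

#' Estimate the covered distance by all five methods
#'
#' Preprocesses the trace with [remove_speed_outliers()] and computes the
#' strapdown (`D_S`), coordinate (`D_C`), lap-count (`D_L`) and the two
#' hybrid (`D_LS`, `D_LC`) distance estimates. When the latitude signal
#' yields fewer than two peaks, the lap-based entries are `NA`.
#'
#' @param trace A raw `gnss_trace`.
#' @param lap_length_m Lap length (m).
#' @param min_lap_time_s Minimum plausible lap duration (s).
#' @param window_s,k_sd Outlier-filter parameters.
#' @return Named numeric vector `c(D_S=, D_C=, D_L=, D_LS=, D_LC=)` (m).
#' @export
estimate_distances <- function(trace, lap_length_m = 400, min_lap_time_s = 50,
                               window_s = 60, k_sd = 2) {
  trace <- remove_speed_outliers(trace, window_s = window_s, k_sd = k_sd)
  rate <- 1 / median(diff(trace$time_s))
  ds <- distance_strapdown(trace)
  dc <- distance_coordinates(trace)
  dec <- tryCatch(
    detect_lap_peaks(trace$lat_deg, rate_hz = rate,
                     min_lap_time_s = min_lap_time_s),
    error = function(e) NULL)
  if (is.null(dec)) {
    dl <- dls <- dlc <- NA_real_
  } else {
    dl <- distance_lap_count(dec, lap_length_m)
    dls <- distance_lap_strapdown(trace, dec, lap_length_m)
    dlc <- distance_lap_coordinates(trace, dec, lap_length_m)
  }
  c(D_S = ds, D_C = dc, D_L = dl, D_LS = dls, D_LC = dlc)
}

#' Compare distance estimators against a reference
#'
#' For each estimation method, summarises the agreement with the reference
#' distance across participants: mean absolute error (m and %), signed bias,
#' coefficient of variation of the percentage error, Bland-Altman 95% limits
#' of agreement, and the median and interquartile range of percentage errors.
#'
#' @param estimates Numeric matrix or data frame, participants x methods (m).
#' @param reference Numeric vector of reference distances (m), one per
#'   participant.
#' @return A data frame of class `distance_error_report`, one row per method
#'   with columns `method`, `mae_m`, `mae_pct`, `bias_m`, `cv_pct`,
#'   `loa_upper_m`, `loa_lower_m`, `median_err_pct`, `iqr_err_pct`.
#' @export
compare_methods <- function(estimates, reference) {
  est <- as.matrix(estimates)
  if (nrow(est) != length(reference))
    stop("`estimates` rows and `reference` length differ", call. = FALSE)
  out <- lapply(colnames(est), function(m) {
    e <- est[, m]
    diff_m <- e - reference
    err_pct <- diff_m / reference * 100
    ok <- is.finite(diff_m)
    d <- diff_m[ok]; p <- err_pct[ok]
    data.frame(
      method = m,
      mae_m = mean(abs(d)),
      mae_pct = mean(abs(p)),
      bias_m = mean(d),
      cv_pct = sd(p),
      loa_upper_m = mean(d) + 1.96 * sd(d),
      loa_lower_m = mean(d) - 1.96 * sd(d),
      median_err_pct = median(p),
      iqr_err_pct = unname(diff(quantile(p, c(0.25, 0.75)))),
      n = sum(ok),
      stringsAsFactors = FALSE
    )
  })
  rep <- do.call(rbind, out)
  class(rep) <- c("distance_error_report", "data.frame")
  rep
}

check_gnss <- function(trace) {
  if (!all(c("time_s", "speed_ms") %in% names(trace)))
    stop("not a GNSS trace: needs `time_s` and `speed_ms` columns",
         call. = FALSE)
  if (is.unsorted(trace$time_s, strictly = TRUE))
    stop("trace timestamps must be strictly increasing", call. = FALSE)
  invisible(trace)
}
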