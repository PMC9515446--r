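#' Synchronization lag between two acceleration signals
#'
#' Cross-correlates the (demeaned) acceleration norms of two sensors that
#' recorded the same shock event and returns the time by which the second
#' signal lags the first. When the peak normalized correlation falls below
#' `min_cor` the signals are considered unrelated and a warning is raised.
#'
#' @param accel_a,accel_b Numeric acceleration-norm series at the same rate.
#' @param rate_hz Sampling rate (Hz).
#' @param max_lag_s Search range (s).
#' @param min_cor Minimum acceptable peak correlation.
#' @return Lag in seconds (positive when `accel_b` lags `accel_a`), with the
#'   peak correlation attached as attribute `peak_cor`.
#' @export
sync_lag <- function(accel_a, accel_b, rate_hz, max_lag_s = 5, min_cor = 0.5) {
  a <- as.numeric(accel_a); b <- as.numeric(accel_b)
  lag_max <- min(round(max_lag_s * rate_hz),
                 min(length(a), length(b)) - 2L)
  cc <- stats::ccf(a, b, lag.max = lag_max, plot = FALSE, demean = TRUE)
  k <- cc$lag[which.max(cc$acf)]
  peak <- max(cc$acf)
  if (peak < min_cor)
    warning("peak cross-correlation ", signif(peak, 3),
            " below threshold: signals may be unrelated", call. = FALSE)
  # ccf(a, b) at lag k is cor(a[t+k], b[t]); if b is a delayed by d the
  # maximum sits at k = -d, so b lags a by -k.
  structure(-k / rate_hz, peak_cor = peak)
}

#' Locate the 12-minute run window
#'
#' Finds the run onset as the first instant at which the foot-IMU
#' acceleration norm shows sustained activity (rolling sd above
#' `accel_sd_thresh`) while the GNSS ground speed exceeds `speed_thresh` for
#' at least `sustain_s` seconds, then returns `(start, start + duration_s)`.
#'
#' @param imu A `foot_imu_trace` (columns `time_s`, `acc_*_g`).
#' @param gnss A `gnss_trace` (columns `time_s`, `speed_ms`).
#' @param duration_s Run duration (s).
#' @param accel_sd_thresh Rolling (1 s) sd threshold on acceleration norm (g).
#' @param speed_thresh Ground-speed threshold (m/s).
#' @param sustain_s Minimum sustained activity (s).
#' @return Numeric `c(start, end)` in seconds.
#' @export
segment_run <- function(imu, gnss, duration_s = 720,
                        accel_sd_thresh = 0.1, speed_thresh = 1.5,
                        sustain_s = 5) {
  norm <- sqrt(imu$acc_x_g^2 + imu$acc_y_g^2 + imu$acc_z_g^2)
  # per-second grid shared by both sensors
  secs <- seq(floor(min(imu$time_s)), ceiling(max(imu$time_s)) - 1)
  bin <- findInterval(imu$time_s, secs)
  sd_by_sec <- tapply(norm, bin, sd)
  imu_active <- rep(FALSE, length(secs))
  imu_active[as.integer(names(sd_by_sec))] <- sd_by_sec > accel_sd_thresh
  sp <- approx(gnss$time_s, gnss$speed_ms, xout = secs + 0.5, rule = 2)$y
  active <- imu_active & sp > speed_thresh
  r <- rle(active)
  ends <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= sustain_s)
  if (!length(hit))
    stop("no sustained run onset found", call. = FALSE)
  start <- secs[ends[hit[1]] - r$lengths[hit[1]] + 1]
  c(start = start, end = start + duration_s)
}

#' Detect mid-swing peaks in a sagittal angular-velocity signal
#'
#' Mid-swing peaks delimit gait cycles. Peaks must exceed
#' `prominence_frac` of the 90th-percentile swing amplitude; a refractory
#' period of 0.4 times the median inter-peak interval (estimated in a first
#' pass with `min_sep_s`) suppresses secondary maxima.
#'
#' @param gyro_sagittal Sagittal angular velocity (deg/s).
#' @param rate_hz Sampling rate (Hz).
#' @param prominence_frac Height threshold as a fraction of the
#'   90th-percentile amplitude.
#' @param min_sep_s First-pass minimum peak separation (s).
#' @return Mid-swing times in seconds (numeric, possibly empty).
#' @export
detect_midswings <- function(gyro_sagittal, rate_hz = 512,
                             prominence_frac = 0.4, min_sep_s = 0.3) {
  x <- as.numeric(gyro_sagittal)
  if (!length(x) || max(x) <= 0 || max(x) == min(x)) return(numeric(0))
  height <- prominence_frac * unname(quantile(x[x > 0], 0.9))
  if (height <= 0) return(numeric(0))
  find <- function(sep_s) {
    pk <- pracma::findpeaks(x, minpeakheight = height,
                            minpeakdistance = max(1L, round(sep_s * rate_hz)))
    if (is.null(pk)) integer(0) else sort(pk[, 2])
  }
  idx <- find(min_sep_s)
  if (length(idx) >= 3) {
    gt_med <- median(diff(idx)) / rate_hz
    idx <- find(0.4 * gt_med)
  }
  (idx - 1) / rate_hz
}

#' Per-cycle gait temporal parameters from a raw foot-IMU trace
#'
#' For each gait cycle (delimited by consecutive mid-swing peaks) the gait
#' cycle time is the inter-mid-swing interval; the contact phase is the
#' longest run of samples whose gyroscope norm stays below `still_thresh`
#' (the foot is nearly stationary on the ground); swing time is
#' `GT - CT`. Flight time is estimated as `GT/2 - CT` (clamped at zero), the
#' symmetric-gait approximation for single-foot data. Cycles without a
#' detectable stationary phase of at least `min_still_s` are flagged invalid
#' and excluded. Peak swing velocity is taken as the maximum gyroscope norm
#' in the cycle (an approximation to the orientation-derived value).
#'
#' @param imu A `foot_imu_trace`.
#' @param midswing_times Output of [detect_midswings()] (s).
#' @param still_thresh Gyro-norm stillness threshold (deg/s).
#' @param min_still_s Minimum stance duration accepted (s).
#' @return A data frame with one row per valid cycle: `time_s`, `ct_ms`,
#'   `ft_ms`, `st_ms`, `gt_ms`, `psv_degs`; the number of excluded cycles is
#'   attached as attribute `n_invalid`.
#' @export
temporal_parameters <- function(imu, midswing_times, still_thresh = 50,
                                min_still_s = 0.05) {
  gn <- sqrt(imu$gyro_x_degs^2 + imu$gyro_y_degs^2 + imu$gyro_z_degs^2)
  t <- imu$time_s
  rate <- 1 / median(diff(t))
  nms <- length(midswing_times)
  if (nms < 2)
    return(structure(empty_cycles(), n_invalid = 0L))
  rows <- vector("list", nms - 1L)
  n_invalid <- 0L
  for (k in seq_len(nms - 1L)) {
    t0 <- midswing_times[k]; t1 <- midswing_times[k + 1L]
    gt_ms <- (t1 - t0) * 1000
    i0 <- max(1L, 1L + floor(t0 * rate)); i1 <- min(length(t), 1L + floor(t1 * rate))
    still <- gn[i0:i1] < still_thresh
    r <- rle(still)
    if (!any(r$values & r$lengths >= min_still_s * rate)) {
      n_invalid <- n_invalid + 1L
      next
    }
    best <- which.max(ifelse(r$values, r$lengths, 0L))
    ct_ms <- r$lengths[best] / rate * 1000
    st_ms <- gt_ms - ct_ms
    ft_ms <- max(0, gt_ms / 2 - ct_ms)
    rows[[k]] <- data.frame(time_s = t0, ct_ms = ct_ms, ft_ms = ft_ms,
                            st_ms = st_ms, gt_ms = gt_ms,
                            psv_degs = max(gn[i0:i1]))
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) out <- empty_cycles()
  rownames(out) <- NULL
  structure(out, n_invalid = n_invalid)
}

empty_cycles <- function() {
  data.frame(time_s = numeric(0), ct_ms = numeric(0), ft_ms = numeric(0),
             st_ms = numeric(0), gt_ms = numeric(0), psv_degs = numeric(0))
}

#' Duty factor
#'
#' Percentage ratio of contact time to gait cycle time.
#'
#' @param ct_ms,gt_ms Contact and gait cycle time (ms), vectorised.
#' @return Duty factor in percent.
#' @export
duty_factor <- function(ct_ms, gt_ms) {
  if (any(gt_ms <= 0)) stop("`gt_ms` must be positive", call. = FALSE)
  ct_ms / gt_ms * 100
}

#' Vertical stiffness from the sine-force spring-mass model
#'
#' Models the vertical ground reaction force during contact as a half sine
#' of duration `t_c`. The peak force follows from the impulse balance over
#' one step, `F_max = m g (pi/2) (t_f / t_c + 1)`, and the vertical
#' centre-of-mass displacement at mid-stance is
#' `dz = F_max t_c^2 / (m pi^2) - g t_c^2 / 8`. Vertical stiffness is
#' `F_max / dz`, reported in kN/m. Non-physical inputs (dz <= 0) yield `NA`.
#'
#' @param ct_s Contact time (s), vectorised.
#' @param ft_s Flight time (s).
#' @param mass_kg Body mass (kg).
#' @return Vertical stiffness in kN/m (`NA` where the model degenerates).
#' @export
vertical_stiffness <- function(ct_s, ft_s, mass_kg) {
  if (any(mass_kg <= 0)) stop("`mass_kg` must be positive", call. = FALSE)
  if (any(ct_s <= 0)) stop("`ct_s` must be positive", call. = FALSE)
  if (any(ft_s < 0)) stop("`ft_s` must be >= 0", call. = FALSE)
  f_max <- mass_kg * G_ACCEL * (pi / 2) * (ft_s / ct_s + 1)
  dz <- f_max * ct_s^2 / (mass_kg * pi^2) - G_ACCEL * ct_s^2 / 8
  vs <- f_max / dz / 1000
  vs[dz <= 0] <- NA_real_
  vs
}

#' Symmetry index
#'
#' `SI = 2 |X_L - X_R| / (X_L + X_R) * 100`, bounded in `[0, 200]` and zero
#' iff the two sides are equal. Symmetric under left/right exchange and
#' invariant to a common positive scaling.
#'
#' @param x_left,x_right Left and right parameter values (vectorised).
#' @return Symmetry index in percent.
#' @export
symmetry_index <- function(x_left, x_right) {
  s <- x_left + x_right
  if (any(s <= 0)) stop("`x_left + x_right` must be positive", call. = FALSE)
  2 * abs(x_left - x_right) / s * 100
}

#' Pair left/right cycles and build the analysis series
#'
#' Pairs left- and right-foot cycles by nearest start time (maximum offset
#' half a cycle), computes per-pair symmetry indices for CT, FT, ST and PSV,
#' plus the gait-cycle-time SI used as a validity check (its median should be
#' near zero; a warning is raised above `gt_si_max`). Downstream metric
#' extraction uses only the right-foot parameter values, with duty factor
#' added and, when absent, vertical stiffness computed from CT/FT and the
#' participant's mass.
#'
#' @param left,right Per-foot cycle data frames (`time_s`, `ct_ms`, `ft_ms`,
#'   `st_ms`, `gt_ms`, optionally `vs_knm`, `fsa_deg`, `fea_deg`,
#'   `psv_degs`).
#' @param mass_kg Participant mass (kg), used when `vs_knm` is missing.
#' @param gt_si_max Validity threshold on the median GT symmetry index (%).
#' @return A list of class `gait_cycle_series`: `cycles` (right-foot cycles
#'   with `df_pct` and `vs_knm`), `symmetry` (per-pair `time_s`, `ct_si`,
#'   `ft_si`, `st_si`, `psv_si`, `gt_si`), `valid` (logical),
#'   `n_unpaired` (count of dropped unpaired cycles).
#' @export
build_cycle_series <- function(left, right, mass_kg = NULL, gt_si_max = 2) {
  stopifnot(nrow(right) > 0)
  right <- right[order(right$time_s), ]
  left <- left[order(left$time_s), ]
  if (!"vs_knm" %in% names(right)) {
    if (is.null(mass_kg))
      stop("`mass_kg` is required to compute vertical stiffness", call. = FALSE)
    right$vs_knm <- vertical_stiffness(right$ct_ms / 1000, right$ft_ms / 1000,
                                       mass_kg)
  }
  right$df_pct <- duty_factor(right$ct_ms, right$gt_ms)

  # nearest-start pairing within half a cycle (left foot strikes mid-cycle,
  # so match left cycle k to the right cycle whose window contains it)
  n_un <- 0L
  pairs <- NULL
  if (nrow(left)) {
    j <- findInterval(left$time_s, right$time_s)
    ok <- j >= 1
    offs <- left$time_s - right$time_s[pmax(j, 1)]
    ok <- ok & offs >= 0 & offs <= right$gt_ms[pmax(j, 1)] / 1000
    # one left cycle per right cycle
    idx <- which(ok)
    ok[idx[duplicated(j[idx])]] <- FALSE
    n_un <- sum(!ok) + sum(!seq_len(nrow(right)) %in% j[ok])
    if (any(ok)) {
      L <- left[ok, ]; R <- right[j[ok], ]
      pairs <- data.frame(
        time_s = R$time_s,
        ct_si = symmetry_index(L$ct_ms, R$ct_ms),
        ft_si = si_or_zero(L$ft_ms, R$ft_ms),
        st_si = symmetry_index(L$st_ms, R$st_ms),
        psv_si = if (all(c("psv_degs") %in% names(L)))
          symmetry_index(L$psv_degs, R$psv_degs) else NA_real_,
        gt_si = symmetry_index(L$gt_ms, R$gt_ms)
      )
    }
  }
  if (is.null(pairs))
    pairs <- data.frame(time_s = numeric(0), ct_si = numeric(0),
                        ft_si = numeric(0), st_si = numeric(0),
                        psv_si = numeric(0), gt_si = numeric(0))
  valid <- nrow(pairs) > 0 && median(pairs$gt_si) <= gt_si_max
  if (!valid && nrow(pairs) > 0)
    warning("median gait-cycle-time SI ", signif(median(pairs$gt_si), 3),
            "% exceeds ", gt_si_max, "%: pairing may be unreliable",
            call. = FALSE)
  structure(list(cycles = right, symmetry = pairs, valid = valid,
                 n_unpaired = n_un),
            class = "gait_cycle_series")
}

# SI with a zero-sum guard: both sides zero (e.g. flight time clamped at 0)
# counts as perfectly symmetric.
si_or_zero <- function(l, r) {
  s <- l + r
  out <- numeric(length(s))
  nz <- s > 0
  out[nz] <- 2 * abs(l[nz] - r[nz]) / s[nz] * 100
  out
}

#' Split a synthetic gait stream into the paired analysis series
#'
#' Convenience bridge from the per-cycle stream format (long, with a `side`
#' column) to [build_cycle_series()].
#'
#' @param stream A [generate_gait_stream()] data frame.
#' @param mass_kg Participant mass (kg); only needed if the stream lacks
#'   `vs_knm`.
#' @param gt_si_max Validity threshold on the median GT symmetry index (%).
#' @return A `gait_cycle_series` (see [build_cycle_series()]).
#' @export
cycle_series_from_stream <- function(stream, mass_kg = NULL, gt_si_max = 2) {
  stopifnot("side" %in% names(stream))
  build_cycle_series(stream[stream$side == "L", , drop = FALSE],
                     stream[stream$side == "R", , drop = FALSE],
                     mass_kg = mass_kg, gt_si_max = gt_si_max)
}
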