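#' Ground-truth gait model for the synthetic stream generator
#'
#' Per-parameter baseline, linear fatigue drift (units per minute),
#' short-term per-cycle noise sd and left/right additive offset for the eight
#' primary parameters: contact time (CT), flight time (FT), swing time (ST),
#' gait cycle time (GT), vertical stiffness (VS), foot strike angle (FSA),
#' foot eversion angle (FEA) and peak swing velocity (PSV). Swing time is
#' tied to the others (`ST = GT - CT` at baseline and per generated cycle).
#'
#' The `"fatigued"` preset applies drifts in the direction acute fatigue
#' pushes running form: contact time rises while flight time, foot strike
#' angle and vertical stiffness fall. The `"steady"` preset has no drift.
#' Baseline magnitudes are plausible literature values for trained runners
#' (no per-parameter cohort distributions are published for this protocol);
#' all are overridable.
#'
#' `planted_effects` optionally links parameters to a participant's
#' performance: a data frame with columns `metric` (canonical metric name,
#' e.g. `"muCT_t"`), `target` (cohort column, e.g. `"mas_kmh"`) and `coef`
#' (metric units per km/h). When a stream is generated for a participant,
#' the baseline (mean metrics), drift (slope/delta metrics) or noise sd
#' (variability metrics) of the named parameter is shifted by
#' `coef * (target - ref)` with `ref` the reference speed in `ref_levels`.
#'
#' @param preset `"steady"` or `"fatigued"`.
#' @param baseline,drift,noise_sd,side_offset Named numeric vectors over
#'   `c("ct","ft","st","gt","vs","fsa","fea","psv")` overriding the preset
#'   (units of the parameter; drift per minute).
#' @param planted_effects `NULL` or the data frame described above.
#' @param ref_levels Named reference levels (km/h) for planted effects.
#' @return An object of class `gait_model_truth`.
#' @export
gait_model_truth <- function(preset = c("steady", "fatigued"),
                             baseline = NULL, drift = NULL,
                             noise_sd = NULL, side_offset = NULL,
                             planted_effects = NULL,
                             ref_levels = c(mas_kmh = 16, svt2_kmh = 14,
                                            cas_kmh = 14)) {
  preset <- match.arg(preset)
  pars <- c("ct", "ft", "st", "gt", "vs", "fsa", "fea", "psv")
  base <- c(ct = 250, ft = 100, st = 450, gt = 700, vs = 25,
            fsa = 15, fea = 5, psv = 600)
  drf <- if (preset == "fatigued")
    c(ct = 1.5, ft = -1, st = -1, gt = 0.5, vs = -0.2,
      fsa = -0.3, fea = 0.05, psv = -2)
  else c(ct = 0, ft = 0, st = 0, gt = 0, vs = 0, fsa = 0, fea = 0, psv = 0)
  nsd <- c(ct = 8, ft = 8, st = 10, gt = 10, vs = 1.5,
           fsa = 1.5, fea = 1, psv = 20)
  off <- c(ct = 4, ft = 3, st = -4, gt = 0, vs = 0, fsa = 0.5,
           fea = 0.3, psv = 15)
  merge_in <- function(x, o) { if (!is.null(o)) x[names(o)] <- o; x }
  base <- merge_in(base, baseline)
  drf <- merge_in(drf, drift)
  nsd <- merge_in(nsd, noise_sd)
  off <- merge_in(off, side_offset)
  # swing time is cycle minus contact, at baseline and in drift/offset
  base["st"] <- base["gt"] - base["ct"]
  drf["st"] <- drf["gt"] - drf["ct"]
  off["st"] <- off["gt"] - off["ct"]
  if (any(base[c("ct", "st", "gt")] <= 0) || base["ft"] < 0)
    stop("baselines must satisfy CT, ST, GT > 0 and FT >= 0", call. = FALSE)
  if (any(nsd < 0)) stop("noise sds must be >= 0", call. = FALSE)
  if (preset == "fatigued" &&
      !(drf["ct"] > 0 && drf["ft"] < 0 && drf["fsa"] < 0 && drf["vs"] < 0))
    stop("the fatigued preset requires CT drift > 0 and FT/FSA/VS drift < 0",
         call. = FALSE)
  if (!is.null(planted_effects)) {
    stopifnot(is.data.frame(planted_effects),
              all(c("metric", "target", "coef") %in% names(planted_effects)))
  }
  structure(
    list(baseline = base[pars], drift = drf[pars], noise_sd = nsd[pars],
         side_offset = off[pars], planted_effects = planted_effects,
         ref_levels = ref_levels, preset = preset),
    class = "gait_model_truth"
  )
}

# Shift a truth object according to its planted-effect map and one
# participant record.
apply_planted_effects <- function(truth, record) {
  pe <- truth$planted_effects
  if (is.null(pe) || nrow(pe) == 0) return(truth)
  for (i in seq_len(nrow(pe))) {
    nm <- parse_metric_name(pe$metric[i])
    par <- tolower(nm$parameter)
    if (!par %in% names(truth$baseline))
      stop("planted effect on parameter without a generator model: ",
           pe$metric[i], call. = FALSE)
    dev <- record[[pe$target[i]]] - truth$ref_levels[[pe$target[i]]]
    shift <- pe$coef[i] * dev
    if (nm$feature == "mu" && nm$segment != "d") {
      truth$baseline[par] <- truth$baseline[par] + shift
    } else if (nm$feature == "sd") {
      truth$noise_sd[par] <- max(0, truth$noise_sd[par] + shift)
    } else {
      # slope features and all Delta-segment features plant on the drift;
      # a Delta metric spans ~9 minutes between segment centres
      div <- if (nm$feature == "mu" && nm$segment == "d") 9 else 1
      truth$drift[par] <- truth$drift[par] + shift / div
    }
  }
  truth$baseline["st"] <- truth$baseline["gt"] - truth$baseline["ct"]
  truth$drift["st"] <- truth$drift["gt"] - truth$drift["ct"]
  truth
}

#' Generate a per-cycle gait parameter stream for one participant
#'
#' Simulates ~12 minutes of left and right foot gait cycles. Right-foot
#' cycle start times advance by the evolving gait cycle time; per-cycle
#' parameter values are `baseline + drift * elapsed_minutes + noise`, with
#' the conservation `GT = CT + ST` enforced exactly per cycle. Left-foot
#' values equal the right-foot values plus the configured side offset (which
#' drives the symmetry indices downstream) and start half a cycle later.
#'
#' @param record One cohort row (used for planted performance effects).
#' @param truth A [gait_model_truth()].
#' @param duration_s Stream duration (s).
#' @param seed Integer seed.
#' @return A data frame of class `gait_stream` with columns `time_s`, `side`
#'   (`"L"`/`"R"`), `ct_ms`, `ft_ms`, `st_ms`, `gt_ms`, `vs_knm`, `fsa_deg`,
#'   `fea_deg`, `psv_degs`; the resolved truth object is attached as
#'   attribute `truth`.
#' @export
generate_gait_stream <- function(record, truth = gait_model_truth(),
                                 duration_s = 720, seed = 1L) {
  stopifnot(inherits(truth, "gait_model_truth"))
  truth <- apply_planted_effects(truth, record)
  b <- truth$baseline; dr <- truth$drift; ns <- truth$noise_sd
  off <- truth$side_offset

  stream <- withr_seed(seed, {
    # conservative upper bound on cycle count
    gt_min <- max(100, min(b["gt"], b["gt"] + dr["gt"] * duration_s / 60))
    n_max <- ceiling(duration_s / (gt_min / 1000)) + 2L
    times <- numeric(n_max); gt <- numeric(n_max)
    t <- 0; i <- 0L
    repeat {
      mins <- t / 60
      g <- b["gt"] + dr["gt"] * mins +
        (if (ns["gt"] > 0) rnorm(1, 0, ns["gt"]) else 0)
      if (g <= 0) stop("gait model produced a non-positive cycle time",
                       call. = FALSE)
      if (t + g / 1000 > duration_s) break  # only whole cycles are kept
      i <- i + 1L
      times[i] <- t; gt[i] <- g
      t <- t + g / 1000
    }
    times <- times[seq_len(i)]; gt <- gt[seq_len(i)]
    mins <- times / 60
    draw <- function(p) {
      b[p] + dr[p] * mins + (if (ns[p] > 0) rnorm(i, 0, ns[p]) else 0)
    }
    ct <- pmin(draw("ct"), 0.95 * gt)
    st <- gt - ct
    gt <- ct + st  # re-derive so the conservation identity is bit-exact
    ft <- pmax(0, draw("ft"))
    right <- data.frame(time_s = times, side = "R",
                        ct_ms = ct, ft_ms = ft, st_ms = st, gt_ms = gt,
                        vs_knm = draw("vs"), fsa_deg = draw("fsa"),
                        fea_deg = draw("fea"), psv_degs = draw("psv"),
                        stringsAsFactors = FALSE)
    left <- right
    left$side <- "L"
    left$time_s <- right$time_s + right$gt_ms / 2000
    for (p in c("ct", "ft", "gt", "vs", "fsa", "fea", "psv"))
      left[[paste0(p, "_", col_unit(p))]] <-
        left[[paste0(p, "_", col_unit(p))]] + off[p]
    left$st_ms <- left$gt_ms - left$ct_ms
    left$gt_ms <- left$ct_ms + left$st_ms
    left$ft_ms <- pmax(0, left$ft_ms)
    out <- rbind(right, left)
    out <- out[order(out$time_s, out$side), ]
    rownames(out) <- NULL
    out
  })
  attr(stream, "truth") <- truth
  class(stream) <- c("gait_stream", "data.frame")
  stream
}

col_unit <- function(p) {
  c(ct = "ms", ft = "ms", st = "ms", gt = "ms", vs = "knm",
    fsa = "deg", fea = "deg", psv = "degs")[[p]]
}

#' Synthesize a raw foot-IMU trace from a gait-cycle series
#'
#' Builds a 512 Hz sagittal angular-velocity signal with one dominant
#' mid-swing peak per cycle at the cycle start times of `series`, a moderate
#' swing-phase plateau, and (near-)zero angular velocity during the planted
#' stance windows — plus a 3-axis acceleration channel with an impact burst
#' at each initial contact, so both gait-cycle segmentation and run-onset
#' detection can be exercised against known ground truth.
#'
#' The stance of cycle *i* (contact duration `ct_ms`) starts half a swing
#' time after the mid-swing peak; the mid-swing pulse has the planted
#' amplitude and a width proportional to the swing time.
#'
#' @param series One foot's rows of a [generate_gait_stream()] output
#'   (columns `time_s`, `ct_ms`, `st_ms`, `gt_ms`).
#' @param rate_hz IMU sampling rate (Hz).
#' @param amplitude Mid-swing peak angular velocity (deg/s).
#' @param swing_level Swing-phase plateau angular velocity (deg/s).
#' @param noise_sd White measurement noise on every channel (deg/s or g).
#' @param run_start_s Quiet lead-in before the first cycle (s); at least a
#'   short lead-in is needed for the first mid-swing peak to be detectable.
#' @param seed Integer seed.
#' @return A data frame of class `foot_imu_trace` with columns `time_s`,
#'   `gyro_x/y/z_degs` (sagittal axis = y) and `acc_x/y/z_g`; planted
#'   mid-swing times and stance windows are attached as attribute `planted`.
#' @export
generate_foot_gyro <- function(series, rate_hz = 512, amplitude = 500,
                               swing_level = 150, noise_sd = 0,
                               run_start_s = 1, seed = 1L) {
  if (rate_hz <= 0) stop("`rate_hz` must be positive", call. = FALSE)
  stopifnot(all(c("time_s", "ct_ms", "st_ms", "gt_ms") %in% names(series)))
  n_cyc <- nrow(series)
  dur <- run_start_s +
    (if (n_cyc) max(series$time_s) + max(series$gt_ms) / 1000 else 1) + 1
  time_s <- seq(0, dur, by = 1 / rate_hz)
  n <- length(time_s)
  gy <- numeric(n)
  az <- rep(1, n)  # gravity, in g

  mids <- run_start_s + series$time_s
  stance_on <- numeric(n_cyc); stance_off <- numeric(n_cyc)
  for (k in seq_len(n_cyc)) {
    tm <- mids[k]
    st_s <- series$st_ms[k] / 1000
    ct_s <- series$ct_ms[k] / 1000
    gt_s <- series$gt_ms[k] / 1000
    on <- tm + st_s / 2
    offt <- min(on + ct_s, tm + gt_s)
    stance_on[k] <- on; stance_off[k] <- offt
    i0 <- max(1L, 1L + floor(tm * rate_hz))
    i1 <- min(n, 1L + ceiling((tm + gt_s) * rate_hz) - 1L)
    if (i0 > i1) next
    tt <- time_s[i0:i1]
    swing <- tt < on | tt >= offt
    seg <- ifelse(swing, swing_level, 0)
    if (amplitude > 0) {
      w <- max(st_s / 8, 2 / rate_hz)
      seg <- seg + amplitude * exp(-0.5 * ((tt - tm) / w)^2) * swing
    }
    gy[i0:i1] <- seg
    # impact burst on the vertical accelerometer at initial contact (50 ms)
    j0 <- max(1L, 1L + floor(on * rate_hz))
    j1 <- min(n, j0 + ceiling(0.05 * rate_hz))
    if (amplitude > 0 && j0 <= j1) {
      td <- time_s[j0:j1] - on
      az[j0:j1] <- az[j0:j1] + 3 * exp(-td / 0.015)
    }
  }
  trace <- withr_seed(seed, {
    add_noise <- function(x, s) if (s > 0) x + rnorm(n, 0, s) else x
    data.frame(
      time_s = time_s,
      gyro_x_degs = add_noise(numeric(n), noise_sd),
      gyro_y_degs = add_noise(gy, noise_sd),
      gyro_z_degs = add_noise(numeric(n), noise_sd),
      acc_x_g = add_noise(numeric(n), noise_sd / 100),
      acc_y_g = add_noise(numeric(n), noise_sd / 100),
      acc_z_g = add_noise(az, noise_sd / 100)
    )
  })
  attr(trace, "planted") <- list(midswing_times = mids,
                                 stance_on = stance_on,
                                 stance_off = stance_off,
                                 amplitude = amplitude,
                                 run_start_s = run_start_s)
  class(trace) <- c("foot_imu_trace", "data.frame")
  trace
}
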