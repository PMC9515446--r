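# Shared fixtures and independent oracles, built in code at test time.

# All 175 canonical metric names, straight from the grid definition.
all_metric_names <- function() {
  g <- expand.grid(f = c("mu", "sd", "m"),
                   p = c("CT", "FT", "ST", "GT", "VS", "FSA", "FEA", "PSV",
                         "DF", "CTSI", "FTSI", "STSI", "PSVSI"),
                   s = c("t", "sy", "s", "e", "d"),
                   stringsAsFactors = FALSE)
  g <- g[!(g$f == "sd" & g$p %in% c("CTSI", "FTSI", "STSI", "PSVSI")), ]
  format_metric_name(g$f, g$p, g$s)
}

# A noiseless, drift-free gait-model truth (deterministic streams).
quiet_truth <- function(...) {
  gait_model_truth("steady",
                   noise_sd = c(ct = 0, ft = 0, st = 0, gt = 0, vs = 0,
                                fsa = 0, fea = 0, psv = 0),
                   side_offset = c(ct = 0, ft = 0, st = 0, gt = 0, vs = 0,
                                   fsa = 0, fea = 0, psv = 0),
                   ...)
}

# Minimal participant-like record for the trajectory generator.
const_speed_record <- function(speed_ms) list(cas_kmh = speed_ms * 3.6)

# Noise-free constant-speed trace (the 3,024 m reference run at 4.2 m/s).
clean_trace <- function(speed_ms = 4.2, duration_s = 720, seed = 1) {
  generate_track_trajectory(const_speed_record(speed_ms),
                            noise = noise_preset("none"),
                            duration_s = duration_s,
                            decay_frac = 0, start_ramp = 1, end_kick = 0,
                            seed = seed)
}

# Planted-effect cohort matrix for selection-pipeline recovery tests:
# z-independent Gaussian metrics, y = X[, planted] %*% coef + noise.
planted_matrix <- function(n = 40, planted = c(muVS_t = 2, sdCT_t = -2,
                                               muCT_d = 2),
                           n_noise = 30, noise_sd = 0.2, seed = 1) {
  set.seed(seed)
  nm <- c(names(planted),
          sample(setdiff(all_metric_names(), names(planted)), n_noise))
  X <- matrix(rnorm(n * length(nm)), n, dimnames = list(NULL, nm))
  y <- as.numeric(X[, names(planted)] %*% planted + rnorm(n, 0, noise_sd))
  list(X = X, y = y, planted = planted)
}

# Independent sine-force spring-mass oracle: numerically integrate
# m z'' = F_max sin(pi t / t_c) - m g from the landing velocity -g t_f / 2
# and read the centre-of-mass drop at its lowest point.
vs_ode_oracle <- function(tc_s, tf_s, mass_kg, n_steps = 2000) {
  f_max <- mass_kg * 9.81 * (pi / 2) * (tf_s / tc_s + 1)
  deriv <- function(t, y, p)
    list(c(y[2], f_max * sin(pi * t / tc_s) / mass_kg - 9.81))
  out <- deSolve::ode(c(z = 0, v = -9.81 * tf_s / 2),
                      seq(0, tc_s, length.out = n_steps + 1), deriv, NULL)
  f_max / (-min(out[, "z"])) / 1000
}

# Polyline arc length of a trace via the Haversine formula -- the oracle for
# generated trajectories.
polyline_length_m <- function(trace) {
  n <- nrow(trace)
  sum(haversine_m(trace$lat_deg[-n], trace$lon_deg[-n],
                  trace$lat_deg[-1], trace$lon_deg[-1]))
}
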