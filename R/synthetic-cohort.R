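#' Cohort simulation configuration
#'
#' Describes the statistical structure of a simulated Cooper-test cohort:
#' maximal aerobic speed (MAS) is drawn uniformly over `mas_range`; the speed
#' at the second ventilatory threshold (sVT2) is linearly linked to MAS with
#' Gaussian noise; the reference 12-minute distance follows from the fraction
#' of MAS each runner sustains over the test (the Cooper average speed, CAS).
#'
#' Default values emulate a mixed cohort of highly trained and recreational
#' runners: 33 participants, performance speeds spanning roughly 9-21.5 km/h,
#' and an sVT2-MAS link whose slope/intercept are consistent with the linear
#' distance-to-speed equations shipped in [predict_mas()] and [predict_svt2()].
#'
#' @param n_participants Number of runners (>= 2).
#' @param mas_range Length-2 numeric, low/high MAS in km/h.
#' @param svt2_slope,svt2_intercept Linear link sVT2 = slope * MAS + intercept
#'   (km/h).
#' @param svt2_noise_sd Gaussian noise sd on sVT2 (km/h).
#' @param cas_fraction Fraction of MAS sustained over the 12 minutes, in
#'   (0, 1]. The reference distance is `cas_fraction * MAS * 0.2` km.
#' @param mass_mean,mass_sd Body-mass distribution (kg), truncated at 40 kg.
#' @param seed Integer seed; every generator call is deterministic given it.
#'
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 33L,
                          mas_range = c(10.5, 21.5),
                          svt2_slope = 0.918,
                          svt2_intercept = -0.63,
                          svt2_noise_sd = 0.8,
                          cas_fraction = 0.88,
                          mass_mean = 69,
                          mass_sd = 10,
                          seed = 1L) {
  if (length(n_participants) != 1L || n_participants < 2)
    stop("`n_participants` must be >= 2", call. = FALSE)
  if (length(mas_range) != 2L || mas_range[1] >= mas_range[2])
    stop("`mas_range` must be an increasing (low, high) pair", call. = FALSE)
  if (cas_fraction <= 0 || cas_fraction > 1)
    stop("`cas_fraction` must lie in (0, 1]", call. = FALSE)
  if (svt2_noise_sd < 0) stop("`svt2_noise_sd` must be >= 0", call. = FALSE)
  if (mass_mean <= 0 || mass_sd < 0)
    stop("mass distribution must be positive", call. = FALSE)
  structure(
    list(n_participants = as.integer(n_participants),
         mas_range = as.numeric(mas_range),
         svt2_slope = svt2_slope, svt2_intercept = svt2_intercept,
         svt2_noise_sd = svt2_noise_sd, cas_fraction = cas_fraction,
         mass_mean = mass_mean, mass_sd = mass_sd,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Generate a synthetic cohort of runners
#'
#' Draws one participant record per runner: body mass, MAS, sVT2 (linear in
#' MAS plus noise) and the reference 12-minute distance
#' `dref_km = cas_fraction * MAS * 0.2`. Deterministic for a fixed seed.
#'
#' @param config A [cohort_config()].
#' @return A data frame with columns `id`, `mass_kg`, `mas_kmh`, `svt2_kmh`,
#'   `cas_kmh`, `dref_km`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_participants
  cohort <- withr_seed(config$seed, {
    mas <- runif(n, config$mas_range[1], config$mas_range[2])
    svt2 <- config$svt2_slope * mas + config$svt2_intercept +
      rnorm(n, 0, config$svt2_noise_sd)
    mass <- pmax(40, rnorm(n, config$mass_mean, config$mass_sd))
    data.frame(
      id = sprintf("P%02d", seq_len(n)),
      mass_kg = mass,
      mas_kmh = mas,
      svt2_kmh = svt2,
      cas_kmh = config$cas_fraction * mas,
      dref_km = config$cas_fraction * mas * 0.2,
      stringsAsFactors = FALSE
    )
  })
  cohort
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards.  Keeps all generators deterministic without
# clobbering the session RNG.
withr_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
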