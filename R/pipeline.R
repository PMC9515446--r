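#' Pipeline configuration
#'
#' Declarative configuration for an end-to-end synthetic run: cohort and
#' gait-model settings, every threshold exposed by the upstream modules,
#' stage toggles and the output directory.
#'
#' @param cohort A [cohort_config()].
#' @param truth A [gait_model_truth()].
#' @param noise A [noise_spec()] for the GNSS simulation.
#' @param stages Character subset of
#'   `c("simulate", "distance", "metrics", "select", "predict")`; stages are
#'   executed in this fixed order and later stages require earlier ones.
#' @param lap_length_m,min_lap_time_s,window_s,k_sd Distance-stage knobs.
#' @param r_thresh,r_min,alpha,k_group Selection-stage knobs.
#' @param out_dir Output directory (`NULL` = keep everything in memory).
#' @param seed Master seed; all per-participant seeds derive from it.
#' @return An object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(),
                       truth = gait_model_truth(preset = "fatigued",
                                                planted_effects = default_planted_effects()),
                       noise = noise_preset("field"),
                       stages = c("simulate", "distance", "metrics",
                                  "select", "predict"),
                       lap_length_m = 400, min_lap_time_s = 50,
                       window_s = 60, k_sd = 2,
                       r_thresh = 0.95, r_min = 0.3,
                       alpha = 0.05, k_group = 10,
                       out_dir = NULL, seed = 1L) {
  stages <- match.arg(stages, several.ok = TRUE)
  structure(
    list(cohort = cohort, truth = truth, noise = noise, stages = stages,
         lap_length_m = lap_length_m, min_lap_time_s = min_lap_time_s,
         window_s = window_s, k_sd = k_sd, r_thresh = r_thresh,
         r_min = r_min, alpha = alpha, k_group = k_group,
         out_dir = out_dir, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Default performance-linked gait effects
#'
#' The planted-effect map used by the default pipeline configuration: faster
#' runners have shorter contact and cycle times, higher vertical stiffness
#' and peak swing velocity, less short-term variability and a smaller
#' fatigue-induced contact-time increase — the directions reported for
#' trained versus recreational runners.
#'
#' @return A data frame with columns `metric`, `target`, `coef`.
#' @export
default_planted_effects <- function() {
  data.frame(
    metric = c("muCT_t", "muGT_t", "muVS_t", "muPSV_t", "sdCT_t", "muCT_d"),
    target = "mas_kmh",
    coef = c(-6, -8, 0.9, 12, -0.5, -1.2),
    stringsAsFactors = FALSE
  )
}

#' Run the end-to-end synthetic Cooper-test pipeline
#'
#' Executes the enabled stages in order: simulate the cohort, GNSS traces
#' and gait streams; estimate the covered distance by the five methods and
#' compare them with the simulated reference; extract the 175-metric grid
#' per participant; run the selection pipeline for MAS, sVT2 and CAS and
#' build the biomechanical profile; and fit/evaluate the
#' distance-to-performance models. Re-running with an identical
#' configuration reproduces identical outputs. When `config$out_dir` is
#' set, artifacts are written there as delimited tables plus a plain-text
#' manifest.
#'
#' @param config A [run_config()].
#' @return A list of class `cooper_run` with elements `cohort`, `traces`,
#'   `streams`, `distances` (estimates + error report), `metrics` (cohort
#'   matrix), `selection` (per-variable results + profile), `models`, and
#'   `manifest`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  res <- list(manifest = list(seed = config$seed,
                              stages = config$stages,
                              started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                              counts = list()))

  # --- simulate ---------------------------------------------------------
  cohort <- generate_cohort(config$cohort)
  n <- nrow(cohort)
  traces <- streams <- vector("list", n)
  for (i in seq_len(n)) {
    traces[[i]] <- generate_track_trajectory(
      cohort[i, ], noise = config$noise,
      seed = config$seed * 1000L + i)
    streams[[i]] <- generate_gait_stream(
      cohort[i, ], truth = config$truth,
      seed = config$seed * 1000L + 500L + i)
  }
  names(traces) <- names(streams) <- cohort$id
  res$cohort <- cohort
  res$traces <- traces
  res$streams <- streams
  res$manifest$counts$participants <- n
  if (!"simulate" %in% config$stages) return(finish_run(res, config))

  # --- distance ---------------------------------------------------------
  if ("distance" %in% config$stages) {
    est <- t(vapply(traces, function(tr)
      estimate_distances(tr, lap_length_m = config$lap_length_m,
                         min_lap_time_s = config$min_lap_time_s,
                         window_s = config$window_s, k_sd = config$k_sd),
      numeric(5)))
    # reference from track markings: 10 m resolution
    dref_m <- round(cohort$dref_km * 1000 / 10) * 10
    res$distances <- list(estimates = est, reference_m = dref_m,
                          report = compare_methods(est, dref_m))
  }

  # --- metrics ----------------------------------------------------------
  if ("metrics" %in% config$stages) {
    sets <- lapply(seq_len(n), function(i) {
      ser <- cycle_series_from_stream(streams[[i]],
                                      mass_kg = cohort$mass_kg[i])
      extract_metrics(trim_run(ser, run_start_s = 0))
    })
    names(sets) <- cohort$id
    res$metrics <- cohort_metric_matrix(sets)
    res$metric_sets <- sets
    res$manifest$counts$metrics <- ncol(res$metrics)
  }

  # --- select -----------------------------------------------------------
  if ("select" %in% config$stages) {
    if (is.null(res$metrics)) stop("`select` requires the metrics stage",
                                   call. = FALSE)
    targets <- c(mas = "mas_kmh", svt2 = "svt2_kmh", cas = "cas_kmh")
    sel <- lapply(targets, function(col)
      select_metrics(res$metrics, cohort[[col]],
                     r_thresh = config$r_thresh, r_min = config$r_min,
                     k = config$k_group, alpha = config$alpha))
    names(sel) <- names(targets)
    z <- zscore(res$metrics)
    res$selection <- list(
      per_variable = sel,
      profile = build_profile(lapply(sel, function(s)
        list(lasso = s$lasso, welch = s$welch)), zmat = z))
    res$manifest$counts$funnel <- lapply(sel, `[[`, "counts")
  }

  # --- predict ----------------------------------------------------------
  if ("predict" %in% config$stages) {
    d <- cohort$dref_km
    res$models <- list(
      mas = fit_distance_model(d, cohort$mas_kmh),
      svt2 = fit_distance_model(d, cohort$svt2_kmh),
      cooper = data.frame(id = cohort$id,
                          vo2max = cooper_vo2max(d),
                          mas_cooper = cooper_mas(d),
                          mas_eq = predict_mas(d),
                          svt2_eq = predict_svt2(d)))
  }
  finish_run(res, config)
}

finish_run <- function(res, config) {
  res$manifest$skipped <- setdiff(c("simulate", "distance", "metrics",
                                    "select", "predict"), config$stages)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_cohort_table(res$cohort, file.path(config$out_dir, "cohort.csv"))
    if (!is.null(res$metrics))
      write.csv(res$metrics, file.path(config$out_dir, "metrics.csv"))
    if (!is.null(res$distances)) {
      write.csv(cbind(id = res$cohort$id,
                      as.data.frame(res$distances$estimates),
                      dref_m = res$distances$reference_m),
                file.path(config$out_dir, "distances.csv"), row.names = FALSE)
      write.csv(res$distances$report,
                file.path(config$out_dir, "distance_report.csv"),
                row.names = FALSE)
    }
    if (!is.null(res$selection)) {
      write.csv(res$selection$profile$metrics,
                file.path(config$out_dir, "profile.csv"), row.names = FALSE)
      for (v in names(res$selection$per_variable)) {
        w <- res$selection$per_variable[[v]]$welch
        write.csv(w, file.path(config$out_dir, paste0("welch_", v, ".csv")),
                  row.names = FALSE)
      }
    }
    writeLines(c(
      paste("seed:", res$manifest$seed),
      paste("stages:", paste(config$stages, collapse = ", ")),
      paste("skipped:", paste(res$manifest$skipped, collapse = ", ")),
      paste("participants:", res$manifest$counts$participants)),
      file.path(config$out_dir, "MANIFEST.txt"))
  }
  class(res) <- "cooper_run"
  res
}

#' @export
print.cooper_run <- function(x, ...) {
  cat("<cooper_run>", nrow(x$cohort), "participants\n")
  if (!is.null(x$metrics))
    cat("  metric grid:", nrow(x$metrics), "x", ncol(x$metrics), "\n")
  if (!is.null(x$distances)) {
    cat("  distance MAE (m):\n")
    r <- x$distances$report
    for (i in seq_len(nrow(r)))
      cat(sprintf("    %-5s %8.1f\n", r$method[i], r$mae_m[i]))
  }
  if (!is.null(x$selection)) {
    cat("  profile metrics:",
        paste(x$selection$profile$metrics$name, collapse = ", "), "\n")
  }
  invisible(x)
}
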