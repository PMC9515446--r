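# The 13 biomechanical parameters of the metric grid, in canonical order:
# nine primary (per right-foot cycle) and four asymmetry (per cycle pair).
PRIMARY_PARAMS <- c("CT", "FT", "ST", "GT", "VS", "FSA", "FEA", "PSV", "DF")
ASYM_PARAMS <- c("CTSI", "FTSI", "STSI", "PSVSI")
ALL_PARAMS <- c(PRIMARY_PARAMS, ASYM_PARAMS)
FEATURES <- c("mu", "sd", "m")
SEGMENTS <- c("t", "sy", "s", "e", "d")

# Map parameter token -> column in the cycle/symmetry tables
PARAM_COLS <- c(CT = "ct_ms", FT = "ft_ms", ST = "st_ms", GT = "gt_ms",
                VS = "vs_knm", FSA = "fsa_deg", FEA = "fea_deg",
                PSV = "psv_degs", DF = "df_pct",
                CTSI = "ct_si", FTSI = "ft_si", STSI = "st_si",
                PSVSI = "psv_si")

#' Time segments of the trimmed run
#'
#' Minute bounds (seconds, relative to the run start, half-open intervals)
#' of the four directly measured segments: total `t` = ordinal minutes
#' 2-11, steady `sy` = minutes 5-8, start `s` = 2nd minute, end `e` = 11th
#' minute. The delta segment `d` is derived feature-wise as `e - s`.
#'
#' @return Named list of `c(lo, hi)` bounds in seconds; `d` is `NA`.
#' @export
segment_bounds <- function() {
  list(t = c(60, 660), sy = c(240, 480), s = c(60, 120), e = c(600, 660),
       d = c(NA_real_, NA_real_))
}

# Segment durations in minutes, the denominator of the slope feature.
SEGMENT_MINUTES <- c(t = 10, sy = 4, s = 1, e = 1)

#' Format and parse canonical metric names
#'
#' A metric name combines a feature (`mu`, `sd`, `m`), a parameter token
#' (`CT`, `FT`, `ST`, `GT`, `VS`, `FSA`, `FEA`, `PSV`, `DF`, `CTSI`,
#' `FTSI`, `STSI`, `PSVSI`) and a time segment (`t`, `sy`, `s`, `e`, `d`),
#' e.g. `"muVS_t"`. `style = "unicode"` renders the field's symbols
#' (`"μVSt"`). `parse_metric_name()` inverts both styles;
#' `format(parse(x)) == x` for every canonical name.
#'
#' @param feature,parameter,segment Character vectors (recycled).
#' @param style `"ascii"` (canonical) or `"unicode"`.
#' @return `format_metric_name()`: character names.
#' @export
format_metric_name <- function(feature, parameter, segment,
                               style = c("ascii", "unicode")) {
  style <- match.arg(style)
  stopifnot(all(feature %in% FEATURES), all(parameter %in% ALL_PARAMS),
            all(segment %in% SEGMENTS))
  if (style == "ascii") paste0(feature, parameter, "_", segment)
  else paste0(c(mu = "μ", sd = "σ", m = "m")[feature],
              parameter, segment)
}

#' @rdname format_metric_name
#' @param x Character vector of metric names in either style.
#' @return `parse_metric_name()`: data frame with columns `feature`,
#'   `parameter`, `segment`.
#' @export
parse_metric_name <- function(x) {
  x <- gsub("μ", "mu", gsub("σ", "sd", x))
  m <- regmatches(x, regexec(
    paste0("^(mu|sd|m)(", paste(ALL_PARAMS, collapse = "|"), ")_?(",
           paste(SEGMENTS, collapse = "|"), ")$"), x))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad))
    stop("unparseable metric name(s): ", paste(x[bad], collapse = ", "),
         call. = FALSE)
  data.frame(feature = vapply(m, `[`, "", 2),
             parameter = vapply(m, `[`, "", 3),
             segment = vapply(m, `[`, "", 4),
             stringsAsFactors = FALSE)
}

#' Trim a cycle series to the analysis window
#'
#' Removes the first and last minute of the 12-minute run: cycles whose
#' start time falls in `[60, 660)` seconds relative to `run_start_s` are
#' retained (a cycle belongs to a bin iff its start time lies in the
#' half-open interval).
#'
#' @param series A `gait_cycle_series` or a per-cycle data frame with
#'   `time_s`.
#' @param run_start_s Run start (s) on the series clock.
#' @return Object of the same shape, trimmed.
#' @export
trim_run <- function(series, run_start_s = 0) {
  trim_df <- function(d) {
    if (!nrow(d)) stop("empty cycle series", call. = FALSE)
    rel <- d$time_s - run_start_s
    d[rel >= 60 & rel < 660, , drop = FALSE]
  }
  if (inherits(series, "gait_cycle_series")) {
    series$cycles <- trim_df(series$cycles)
    series$symmetry <- if (nrow(series$symmetry))
      trim_df(series$symmetry) else series$symmetry
    series
  } else trim_df(series)
}

#' Segment features: mean, windowed variability, slope
#'
#' `feature_mean()` is the arithmetic mean over the segment.
#' `feature_variability()` splits the segment into consecutive
#' non-overlapping windows of `window` cycles (any remainder dropped), takes
#' the sample standard deviation of each window and averages the windows;
#' with fewer than one complete window the feature is undefined (`NA`).
#' `feature_slope()` is the difference between the last and first value of
#' the segment divided by the segment duration in minutes; a segment with
#' fewer than two cycles yields 0 by convention.
#'
#' @param values Parameter values over one time segment.
#' @return A scalar feature value.
#' @export
feature_mean <- function(values) {
  if (!length(values)) return(NA_real_)
  mean(values)
}

#' @rdname feature_mean
#' @param window Window length in cycles.
#' @export
feature_variability <- function(values, window = 10) {
  n_win <- length(values) %/% window
  if (n_win < 1) return(NA_real_)
  v <- values[seq_len(n_win * window)]
  win_sd <- vapply(seq_len(n_win),
                   function(k) sd(v[((k - 1) * window + 1):(k * window)]),
                   numeric(1))
  mean(win_sd)
}

#' @rdname feature_mean
#' @param segment_minutes Segment duration in minutes (slope denominator).
#' @export
feature_slope <- function(values, segment_minutes) {
  if (length(values) < 2) return(0)
  (values[length(values)] - values[1]) / segment_minutes
}

#' Categorize a metric
#'
#' Assigns each metric of the grid to exactly one of five categories:
#' *technique* (mean of CT, FT, VS, FSA, FEA, DF outside Delta), *pace*
#' (mean of GT, ST, PSV outside Delta), *regularity* (variability of the
#' nine primary parameters outside Delta), *asymmetry* (mean of the four
#' symmetry indices outside Delta) and *fatigue* (every Delta-segment
#' feature plus the slope feature of every segment). The stated rules
#' partition the grid; should a configuration ever satisfy several rules,
#' precedence technique > pace > regularity > asymmetry > fatigue applies.
#'
#' @param feature,parameter,segment Vectors as in [format_metric_name()]
#'   (recycled to common length).
#' @return Character vector of categories (`"uncategorized"` if no rule
#'   matches).
#' @export
categorize <- function(feature, parameter, segment) {
  n <- max(length(feature), length(parameter), length(segment))
  feature <- rep_len(feature, n); parameter <- rep_len(parameter, n)
  segment <- rep_len(segment, n)
  out <- rep("uncategorized", n)
  non_d <- segment != "d"
  rules <- list(
    technique = feature == "mu" & non_d &
      parameter %in% c("CT", "FT", "VS", "FSA", "FEA", "DF"),
    pace = feature == "mu" & non_d & parameter %in% c("GT", "ST", "PSV"),
    regularity = feature == "sd" & non_d & parameter %in% PRIMARY_PARAMS,
    asymmetry = feature == "mu" & non_d & parameter %in% ASYM_PARAMS,
    fatigue = segment == "d" | feature == "m"
  )
  # reverse order so higher-precedence rules overwrite lower ones
  for (nm in rev(names(rules))) out[rules[[nm]]] <- nm
  out
}

#' Extract the 175-metric grid from one participant's run
#'
#' Applies the three features (mean, windowed variability, slope) to the 13
#' biomechanical parameters over the five time segments. Variability is not
#' computed for the four asymmetry parameters, giving
#' `13 * 5 * 3 - 4 * 5 = 175` metrics. Delta-segment values are the
#' feature-wise difference `feature(e) - feature(s)`.
#'
#' @param series A `gait_cycle_series` (see [build_cycle_series()]), not yet
#'   trimmed.
#' @param run_start_s Run start time on the series clock (s).
#' @param sd_window Variability window length (cycles).
#' @return A data frame of class `metric_set` with columns `name`,
#'   `feature`, `parameter`, `segment`, `category`, `value`. Metrics whose
#'   segment holds no data are `NA` and listed in attribute `missing`.
#' @export
extract_metrics <- function(series, run_start_s = 0, sd_window = 10) {
  stopifnot(inherits(series, "gait_cycle_series"))
  cyc <- series$cycles
  sym <- series$symmetry
  if (!nrow(cyc)) stop("empty cycle series", call. = FALSE)
  bounds <- segment_bounds()
  grid <- expand.grid(feature = FEATURES, parameter = ALL_PARAMS,
                      segment = SEGMENTS, stringsAsFactors = FALSE)
  grid <- grid[!(grid$feature == "sd" & grid$parameter %in% ASYM_PARAMS), ]
  # direct segments first so Delta can difference them
  grid <- grid[order(match(grid$segment, c("t", "sy", "s", "e", "d"))), ]

  seg_values <- function(parameter, seg) {
    src <- if (parameter %in% ASYM_PARAMS) sym else cyc
    rel <- src$time_s - run_start_s
    lo <- bounds[[seg]][1]; hi <- bounds[[seg]][2]
    src[[PARAM_COLS[[parameter]]]][rel >= lo & rel < hi]
  }
  vals <- numeric(nrow(grid))
  key <- paste0(grid$feature, grid$parameter, grid$segment)
  lookup <- function(f, p, s) vals[match(paste0(f, p, s), key)]
  for (i in seq_len(nrow(grid))) {
    f <- grid$feature[i]; p <- grid$parameter[i]; s <- grid$segment[i]
    vals[i] <- if (s == "d") {
      lookup(f, p, "e") - lookup(f, p, "s")
    } else {
      v <- seg_values(p, s)
      switch(f,
             mu = feature_mean(v),
             sd = feature_variability(v, sd_window),
             m = feature_slope(v, SEGMENT_MINUTES[[s]]))
    }
  }
  out <- data.frame(
    name = format_metric_name(grid$feature, grid$parameter, grid$segment),
    feature = grid$feature, parameter = grid$parameter,
    segment = grid$segment,
    category = categorize(grid$feature, grid$parameter, grid$segment),
    value = vals, stringsAsFactors = FALSE)
  # canonical order: segment-major, then parameter, then feature
  out <- out[order(match(out$segment, SEGMENTS),
                   match(out$parameter, ALL_PARAMS),
                   match(out$feature, FEATURES)), ]
  rownames(out) <- NULL
  attr(out, "missing") <- out$name[!is.finite(out$value)]
  class(out) <- c("metric_set", "data.frame")
  out
}

#' Metric set as a named vector
#'
#' @param metrics A `metric_set`.
#' @return Named numeric vector (canonical names).
#' @export
metric_values <- function(metrics) {
  stats::setNames(metrics$value, metrics$name)
}

#' Assemble the cohort-by-metric matrix
#'
#' Binds one [extract_metrics()] result per participant into the
#' participants x metrics matrix used by the selection pipeline.
#'
#' @param metric_sets Named list of `metric_set` objects (names become row
#'   names).
#' @return Numeric matrix, participants x 175.
#' @export
cohort_metric_matrix <- function(metric_sets) {
  stopifnot(length(metric_sets) > 0)
  rows <- lapply(metric_sets, metric_values)
  nms <- names(rows[[1]])
  mat <- do.call(rbind, lapply(rows, function(r) r[nms]))
  colnames(mat) <- nms
  rownames(mat) <- names(metric_sets)
  mat
}
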