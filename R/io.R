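#' Read and write the delimited exchange formats
#'
#' GNSS traces (`time_s, lat_deg, lon_deg, speed_ms`), gait-cycle streams
#' (`time_s, side, ct_ms, ft_ms, st_ms, gt_ms, vs_knm, fsa_deg, fea_deg,
#' psv_degs`) and cohort tables (`id, mass_kg, mas_kmh, svt2_kmh, cas_kmh,
#' dref_km`) travel as comma-separated files with a one-line header.
#'
#' @param x Object to write.
#' @param path File path.
#' @return Readers return the data frame with the class restored; writers
#'   return `path` invisibly.
#' @name cooper_io
NULL

#' @rdname cooper_io
#' @export
write_gnss_trace <- function(x, path) {
  write.csv(x[, c("time_s", "lat_deg", "lon_deg", "speed_ms")], path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname cooper_io
#' @export
read_gnss_trace <- function(path) {
  x <- read.csv(path)
  stopifnot(all(c("time_s", "lat_deg", "lon_deg", "speed_ms") %in% names(x)))
  class(x) <- c("gnss_trace", "data.frame")
  x
}

GAIT_COLS <- c("time_s", "side", "ct_ms", "ft_ms", "st_ms", "gt_ms",
               "vs_knm", "fsa_deg", "fea_deg", "psv_degs")

#' @rdname cooper_io
#' @export
write_gait_stream <- function(x, path) {
  write.csv(x[, GAIT_COLS], path, row.names = FALSE)
  invisible(path)
}

#' @rdname cooper_io
#' @export
read_gait_stream <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(GAIT_COLS %in% names(x)))
  class(x) <- c("gait_stream", "data.frame")
  x
}

#' @rdname cooper_io
#' @export
write_cohort_table <- function(x, path) {
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname cooper_io
#' @export
read_cohort_table <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "mass_kg", "mas_kmh", "svt2_kmh", "dref_km") %in%
                  names(x)))
  x
}
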