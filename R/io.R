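#' Read a particle-detection table
#'
#' Reads a CSV with header columns `frame`, `x`, `y`, `area`, `eccentricity`
#' ('.' decimal, UTF-8), the input of [analyze_tracks()].
#'
#' @param path Path to the CSV file.
#' @return A validated detections data frame.
#' @export
read_detections <- function(path) {
  d <- utils::read.csv(path)
  check_detections(d)
  if (any(d$area < 1)) stop("detection areas must be >= 1 px", call. = FALSE)
  if (any(d$eccentricity < 0 | d$eccentricity >= 1)) {
    stop("eccentricity must lie in [0, 1)", call. = FALSE)
  }
  d
}

#' Write a tracked-trajectory table
#'
#' Writes the output of [analyze_tracks()] as CSV with columns
#' `track_id`, `frame`, `x`, `y`, `motile`, `viable`.
#'
#' @param tracks Data frame from [analyze_tracks()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  utils::write.csv(tracks, path, row.names = FALSE)
  invisible(path)
}

#' Read an OD600 growth table
#'
#' Reads either a single-well CSV (`time_h`, `od600`) or a wide plate layout
#' (`time_h` plus one column per well).
#'
#' @param path Path to the CSV file.
#' @return A data frame whose first column is `time_h`.
#' @export
read_growth <- function(path) {
  d <- utils::read.csv(path)
  if (!"time_h" %in% names(d)) {
    stop("growth table must contain a `time_h` column", call. = FALSE)
  }
  if (ncol(d) < 2L) stop("growth table has no OD columns", call. = FALSE)
  d
}

#' Write a thermal-response curve as CSV
#'
#' Emits columns `T_celsius`, `R`, `class` ('.' decimal, header row).
#'
#' @param x A `thermal_response` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_response_curve <- function(x, path) {
  if (!inherits(x, "thermal_response")) {
    stop("`x` must be a `thermal_response` object", call. = FALSE)
  }
  out <- data.frame(T_celsius = x$curve$T_c, R = x$curve$R,
                    class = x$curve$class)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
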