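## Delimited-text I/O. All files are TSV with a header line and '#' comment
## lines; units are SI (meters, seconds, radians) throughout.

#' Write tracks to a TSV file
#'
#' Columns: `track_id`, `time_s`, `x_m`, `y_m`, `axis_x`, `axis_y`. Values
#' are written with 12 significant digits so a write/read round trip is
#' lossless at that precision.
#'
#' @param tracks an [endo_track()] or list of them.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  if (inherits(tracks, "endo_track")) tracks <- list(tracks)
  dfs <- lapply(seq_along(tracks), function(i) {
    df <- as.data.frame(tracks[[i]])
    cbind(track_id = i, df)
  })
  df <- do.call(rbind, dfs)
  num <- vapply(df, is.numeric, TRUE) & names(df) != "track_id"
  df[num] <- lapply(df[num], function(v) formatC(v, digits = 12,
                                                 format = "g"))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read tracks from a TSV file
#'
#' Expects a header with at least `time_s`, `x_m`, `y_m`; optional `axis_x`,
#' `axis_y` (chain axis, defaults to (1,0)) and `track_id` (splitting the
#' file into several tracks). '#' lines are ignored. Time must be strictly
#' increasing and uniform within each track; violations are reported with
#' the offending row.
#'
#' @param path input file path.
#' @return list of [endo_track()] objects.
#' @export
read_tracks <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  need <- c("time_s", "x_m", "y_m")
  if (!all(need %in% names(df)))
    stop_invalid("track file %s must have columns %s", path,
                 paste(need, collapse = ", "))
  if (anyNA(df[need])) {
    bad <- which(rowSums(is.na(df[need])) > 0)[1]
    stop_invalid("NA value in %s at data row %d", path, bad)
  }
  ids <- if ("track_id" %in% names(df)) df$track_id else rep(1L, nrow(df))
  lapply(split(df, ids), function(d) {
    rev_at <- which(diff(d$time_s) <= 0)
    if (length(rev_at))
      stop_invalid("non-monotone time in %s at data row %d", path,
                   rev_at[1] + 1L)
    axis <- if (all(c("axis_x", "axis_y") %in% names(d)))
      c(d$axis_x[1], d$axis_y[1]) else c(1, 0)
    endo_track(d$time_s, d$x_m, d$y_m, axis = axis)
  })
}

#' Write oscillation records to a TSV file
#'
#' Columns: `freq_hz`, `beta0_rad`, `theta0_rad`, `delta_rad` (plus any
#' extra columns present, e.g. a chain id).
#'
#' @param records an `oscillation_records` data.frame.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_oscillation_records <- function(records, path) {
  utils::write.table(as.data.frame(records), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read oscillation records from a TSV file
#'
#' @param path input file path with header `freq_hz`, `beta0_rad`,
#'   `theta0_rad`, `delta_rad`.
#' @return an `oscillation_records` data.frame.
#' @export
read_oscillation_records <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  need <- c("freq_hz", "beta0_rad", "theta0_rad", "delta_rad")
  if (!all(need %in% names(df)))
    stop_invalid("record file %s must have columns %s", path,
                 paste(need, collapse = ", "))
  class(df) <- c("oscillation_records", "data.frame")
  df
}
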