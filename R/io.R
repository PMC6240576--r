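# Readers/writers for every pipeline artifact. CSV with header is the
# interchange format; times are written to 1 us and amplitudes to 1 nV
# (1e-6 mV), the documented round-trip precision. Frames go to multi-page
# TIFF (see tiff.R) and traces additionally to a simple two-column binary
# container.

fmt6 <- function(x) sprintf("%.6f", x)

write_csv_cols <- function(cols, path) {
  header <- paste(names(cols), collapse = ",")
  n <- if (length(cols)) length(cols[[1L]]) else 0L
  body <- if (n) do.call(paste, c(cols, list(sep = ","))) else character(0)
  writeLines(c(header, body), path)
}

#' Write / read an event table as CSV
#'
#' @param events Event table (see [generate_events()]).
#' @param path File path.
#' @return `read_events_csv()` returns a `transit_events` data frame.
#' @export
write_events_csv <- function(events, path) {
  check_events(events)
  write_csv_cols(list(bead_id = events$bead_id,
                      label = events$label,
                      diameter_um = fmt6(events$diameter_um),
                      velocity_um_s = fmt6(events$velocity_um_s),
                      crossing_time_s = fmt6(events$crossing_time_s),
                      true_amplitude_mV = fmt6(events$true_amplitude_mV)),
                 path)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_events(df)
  class(df) <- c("transit_events", "data.frame")
  df
}

#' Write / read a signal trace as CSV
#'
#' Columns `time_s`, `amplitude_mV`. The sample rate is recovered from the
#' median time step on reading.
#'
#' @param trace A [signal_trace()].
#' @param path File path.
#' @return `read_trace_csv()` returns a [signal_trace()].
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(is_signal_trace(trace))
  write_csv_cols(list(time_s = fmt6(trace_times(trace)),
                      amplitude_mV = fmt6(trace$values)),
                 path)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "amplitude_mV") %in% names(df)))
    pc_stop_validation("trace CSV needs columns time_s, amplitude_mV")
  fs <- if (nrow(df) > 1) 1 / stats::median(diff(df$time_s)) else 1
  signal_trace(df$amplitude_mV, fs, start_time = df$time_s[1])
}

# Binary trace container: magic "PCTR", uint32 version, uint32 n, float64
# start_time, float64 sample_rate, then n little-endian float64
# (time, amplitude) pairs. The header carries the exact sampling metadata so
# the round trip is lossless.
#' Write / read a signal trace in the binary container
#'
#' @inheritParams write_trace_csv
#' @export
write_trace_bin <- function(trace, path) {
  stopifnot(is_signal_trace(trace))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("PCTR"), con)
  writeBin(as.integer(c(1L, length(trace$values))), con,
           size = 4L, endian = "little")
  writeBin(c(trace$start_time, trace$sample_rate), con,
           size = 8L, endian = "little")
  m <- rbind(trace_times(trace), trace$values)
  writeBin(as.numeric(m), con, size = 8L, endian = "little")
  invisible(path)
}

#' @rdname write_trace_bin
#' @export
read_trace_bin <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (rawToChar(readBin(con, "raw", 4L)) != "PCTR")
    pc_stop_validation("not a pulsecount binary trace (bad magic)")
  hdr <- readBin(con, "integer", 2L, size = 4L, endian = "little")
  n <- hdr[2L]
  meta <- readBin(con, "numeric", 2L, size = 8L, endian = "little")
  m <- matrix(readBin(con, "numeric", 2L * n, size = 8L, endian = "little"),
              nrow = 2L)
  signal_trace(m[2, ], meta[2L], start_time = meta[1L])
}

#' Write / read a peak table as CSV
#' @param peaks Data frame from [detect_peaks()].
#' @param path File path.
#' @export
write_peaks_csv <- function(peaks, path) {
  write_csv_cols(list(time_s = fmt6(peaks$time_s),
                      amplitude_mV = fmt6(peaks$amplitude_mV)),
                 path)
  invisible(path)
}

#' @rdname write_peaks_csv
#' @export
read_peaks_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "amplitude_mV") %in% names(df)))
    pc_stop_validation("peaks CSV needs columns time_s, amplitude_mV")
  df
}

#' Write / read per-frame detections as CSV
#' @param detections Data frame from [segment_frame()] / [link_tracks()].
#' @param path File path.
#' @export
write_detections_csv <- function(detections, path) {
  cols <- list(frame_index = detections$frame_index,
               time_s = fmt6(detections$time_s),
               centroid_x = fmt6(detections$centroid_x),
               centroid_y = fmt6(detections$centroid_y),
               pixel_area = detections$pixel_area,
               est_diameter_um = fmt6(detections$est_diameter_um))
  if ("track_id" %in% names(detections))
    cols$track_id <- detections$track_id
  write_csv_cols(cols, path)
  invisible(path)
}

#' @rdname write_detections_csv
#' @export
read_detections_csv <- function(path) utils::read.csv(path,
                                                      stringsAsFactors = FALSE)

#' Write / read a track table as CSV
#' @param tracks Data frame from [build_tracks()].
#' @param path File path.
#' @export
write_tracks_csv <- function(tracks, path) {
  write_csv_cols(list(track_id = tracks$track_id,
                      n_detections = tracks$n_detections,
                      velocity_um_s = fmt6(tracks$velocity_um_s),
                      crossing_time_s = fmt6(tracks$crossing_time_s),
                      est_diameter_um = fmt6(tracks$est_diameter_um),
                      size_class = tracks$size_class),
                 path)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$crossing_time_s <- suppressWarnings(as.numeric(df$crossing_time_s))
  df$velocity_um_s <- suppressWarnings(as.numeric(df$velocity_um_s))
  df
}

#' Write matched pairs as CSV
#' @param pairs `pairs` element of a [match_events()] result.
#' @param path File path.
#' @export
write_pairs_csv <- function(pairs, path) {
  write_csv_cols(list(track_id = pairs$track_id,
                      peak_index = pairs$peak_index,
                      delta_t_s = fmt6(pairs$delta_t_s),
                      amplitude_mV = fmt6(pairs$amplitude_mV),
                      size_class = pairs$size_class),
                 path)
  invisible(path)
}

#' Write a run report as JSON and CSV
#'
#' @param report A [build_report()] result.
#' @param path Output path; `write_report_json()` writes JSON,
#'   `write_report_csv()` a flat CSV with one row per size class.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "run_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, na = "null", dataframe = "rows",
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_report_json
#' @export
write_report_csv <- function(report, path) {
  df <- as.data.frame(report)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
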