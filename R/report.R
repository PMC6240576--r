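#' Build a per-size-class run report
#'
#' Bookkeeping in the style of a bead-counting results table: per size
#' class, the number of beads seen in the video, the number of those matched
#' to an electrical peak and the resulting detection rate; plus the total
#' electrical peak count, the false positives (electrical peaks with no
#' video match) and the mean track velocity. By construction
#' `sum(matched) + false_positives == electrical_peak_count`.
#'
#' @param match_result A [match_events()] result.
#' @param tracks The track table that was matched; only rows with a valid
#'   crossing time count as video detections. Must carry `size_class`.
#' @param peaks The peak table that was matched.
#'
#' @return An object of class `run_report`: list with `classes` (data frame
#'   `size_class`, `video_count`, `matched_count`, `detection_rate_pct`),
#'   `electrical_peak_count`, `false_positive_count`, `mean_velocity_um_s`.
#' @export
build_report <- function(match_result, tracks, peaks) {
  if (!inherits(match_result, "match_result"))
    pc_stop_validation("`match_result` must come from match_events()")
  if (!is.data.frame(tracks) || !"size_class" %in% names(tracks) ||
      (nrow(tracks) && all(is.na(tracks$size_class))))
    pc_stop_validation("`tracks` must carry size-class labels")
  usable <- tracks[!is.na(tracks$crossing_time_s), , drop = FALSE]
  classes <- sort(unique(c(usable$size_class,
                           match_result$pairs$size_class)))
  per_class <- lapply(classes, function(cl) {
    vid <- sum(usable$size_class == cl)
    mat <- sum(match_result$pairs$size_class == cl)
    data.frame(size_class = cl, video_count = vid, matched_count = mat,
               detection_rate_pct = detection_rate(mat, vid))
  })
  classes_df <- do.call(rbind, c(per_class, list(
    data.frame(size_class = character(0), video_count = integer(0),
               matched_count = integer(0), detection_rate_pct = numeric(0)))))
  structure(
    list(classes = classes_df,
         electrical_peak_count = nrow(peaks),
         false_positive_count = length(match_result$unmatched_peaks),
         mean_velocity_um_s = if (nrow(usable))
           mean(usable$velocity_um_s, na.rm = TRUE) else NA_real_),
    class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("Run report\n")
  if (nrow(x$classes)) {
    for (i in seq_len(nrow(x$classes))) {
      r <- x$classes[i, ]
      cat(sprintf("  %-6s video %4d  matched %4d  detection rate %s\n",
                  r$size_class, r$video_count, r$matched_count,
                  if (is.na(r$detection_rate_pct)) "NA"
                  else paste0(r$detection_rate_pct, "%")))
    }
  } else cat("  (no video detections)\n")
  cat(sprintf("  electrical peaks %d (false positives %d)\n",
              x$electrical_peak_count, x$false_positive_count))
  if (!is.na(x$mean_velocity_um_s))
    cat(sprintf("  mean bead velocity %.1f um/s\n", x$mean_velocity_um_s))
  invisible(x)
}

#' @export
as.data.frame.run_report <- function(x, ...) {
  df <- x$classes
  n <- nrow(df)
  df$electrical_peak_count <- rep(x$electrical_peak_count, length.out = n)
  df$false_positive_count <- rep(x$false_positive_count, length.out = n)
  df$mean_velocity_um_s <- rep(x$mean_velocity_um_s, length.out = n)
  df
}
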