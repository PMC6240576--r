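#' Matching settings
#'
#' @param window Maximum allowed absolute time difference between a video
#'   crossing and an electrical peak, in seconds. The default 0.1 s mirrors
#'   the 100 ms coincidence interval within which cross-size mis-assignment
#'   can occur on the reference system.
#'
#' @return An object of class `match_config`.
#' @export
match_config <- function(window = 0.100) {
  check_scalar(window, "window", lower = 0, open_lower = TRUE)
  structure(list(window = as.numeric(window)), class = "match_config")
}

is_match_config <- function(x) inherits(x, "match_config")

#' Match video crossings to electrical peaks
#'
#' Candidate pairs are all (track, peak) combinations with
#' `|t_crossing - t_peak| <= window`; they are accepted greedily in
#' ascending `|dt|`, each track and each peak used at most once. Matching
#' uses time only — never amplitude or size — so the cross-size
#' mis-assignment failure mode of coincident beads is reproduced, not hidden.
#'
#' @param tracks Track table (see [build_tracks()]); rows with `NA`
#'   crossing time are ignored.
#' @param peaks Peak table from [detect_peaks()], sorted by time.
#' @param cfg A [match_config()].
#'
#' @return An object of class `match_result`: list with `pairs` (data frame
#'   `track_id`, `peak_index`, `delta_t_s`, `amplitude_mV`, `size_class`),
#'   `unmatched_tracks` (track ids) and `unmatched_peaks` (row indices into
#'   `peaks`).
#' @export
match_events <- function(tracks, peaks, cfg = match_config()) {
  if (!is_match_config(cfg))
    pc_stop_validation("`cfg` must be a match_config")
  if (!is.data.frame(tracks) || !"crossing_time_s" %in% names(tracks))
    pc_stop_validation("`tracks` must have a `crossing_time_s` column")
  if (!is.data.frame(peaks) || !"time_s" %in% names(peaks))
    pc_stop_validation("`peaks` must have a `time_s` column")
  usable <- which(!is.na(tracks$crossing_time_s))
  np <- nrow(peaks)

  cand <- NULL
  if (length(usable) && np) {
    dt <- abs(outer(tracks$crossing_time_s[usable], peaks$time_s, `-`))
    hit <- which(dt <= cfg$window, arr.ind = TRUE)
    if (nrow(hit)) {
      cand <- data.frame(trow = usable[hit[, 1L]], peak = hit[, 2L],
                         dt = dt[hit])
      cand <- cand[order(cand$dt, cand$trow, cand$peak), , drop = FALSE]
    }
  }

  pair_trow <- integer(0); pair_peak <- integer(0); pair_dt <- numeric(0)
  if (!is.null(cand)) {
    track_used <- rep(FALSE, nrow(tracks))
    peak_used <- rep(FALSE, np)
    for (i in seq_len(nrow(cand))) {
      tr <- cand$trow[i]; pk <- cand$peak[i]
      if (!track_used[tr] && !peak_used[pk]) {
        track_used[tr] <- TRUE
        peak_used[pk] <- TRUE
        pair_trow <- c(pair_trow, tr)
        pair_peak <- c(pair_peak, pk)
        pair_dt <- c(pair_dt, cand$dt[i])
      }
    }
  }

  pairs <- data.frame(
    track_id = if ("track_id" %in% names(tracks))
      tracks$track_id[pair_trow] else pair_trow,
    peak_index = pair_peak,
    delta_t_s = pair_dt,
    amplitude_mV = if ("amplitude_mV" %in% names(peaks))
      peaks$amplitude_mV[pair_peak] else NA_real_,
    size_class = if ("size_class" %in% names(tracks))
      tracks$size_class[pair_trow] else NA_character_,
    stringsAsFactors = FALSE)

  unmatched_tracks <- setdiff(
    if ("track_id" %in% names(tracks)) tracks$track_id[usable] else usable,
    pairs$track_id)
  structure(list(pairs = pairs,
                 unmatched_tracks = unmatched_tracks,
                 unmatched_peaks = setdiff(seq_len(np), pairs$peak_index)),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %d pairs, %d unmatched tracks, %d unmatched peaks\n",
              nrow(x$pairs), length(x$unmatched_tracks),
              length(x$unmatched_peaks)))
  invisible(x)
}

#' Detection rate in percent
#'
#' `100 * matched / video`, rounded to the nearest integer percent (half
#' away from zero). With no video detections the rate is undefined and
#' `NA` is returned rather than 0.
#'
#' @param matched_count Number of video detections matched to a peak.
#' @param video_count Total video detections of the class.
#'
#' @return Integer percent, or `NA_real_` when `video_count` is zero.
#' @examples
#' detection_rate(148, 173)  # 86
#' detection_rate(46, 118)   # 39
#' @export
detection_rate <- function(matched_count, video_count) {
  check_scalar(matched_count, "matched_count", lower = 0, integer = TRUE)
  check_scalar(video_count, "video_count", lower = 0, integer = TRUE)
  if (matched_count > video_count)
    pc_stop_validation("`matched_count` cannot exceed `video_count`")
  if (video_count == 0) return(NA_real_)
  round_half_up(100 * matched_count / video_count)
}

#' Convert a pulse amplitude to a current difference
#'
#' Divides the demodulated output amplitude by the total trans-impedance
#' gain of the measurement chain: `I [nA] = V [mV] / (gain [V/A]) * 1e6`.
#'
#' @param amplitude Amplitude(s) in mV_rms.
#' @param gain Total trans-impedance gain in V/A, `> 0` (default 100 kV/A).
#'
#' @return Current difference(s) in nA.
#' @examples
#' amplitude_to_current(1.6)  # 16 nA at 100 kV/A
#' @export
amplitude_to_current <- function(amplitude, gain = 1e5) {
  if (!is.numeric(amplitude) || any(!is.finite(amplitude)))
    pc_stop_validation("`amplitude` must be finite numeric")
  check_scalar(gain, "gain", lower = 0, open_lower = TRUE)
  amplitude * 1e6 / gain
}

#' Crossover diameter of two bead-size distributions
#'
#' Finds the diameter strictly between the two population means at which the
#' two normal densities `Normal(mean, mean * cv)` are equal, by bracketed
#' root search on the log-density difference (tolerance 1e-6 um). This is
#' the natural boundary for classifying a measured diameter.
#'
#' @param spec_a,spec_b [bead_population()]s with `spec_a$mean_diameter <
#'   spec_b$mean_diameter` and both `cv > 0`.
#'
#' @return Crossover diameter in micrometres.
#' @examples
#' size_crossover(bead_population("6um", 6, 0.07),
#'                bead_population("11um", 11, 0.18))  # about 7.1 um
#' @export
size_crossover <- function(spec_a, spec_b) {
  if (!is_bead_population(spec_a) || !is_bead_population(spec_b))
    pc_stop_validation("`spec_a` and `spec_b` must be bead_population objects")
  if (!(spec_a$mean_diameter < spec_b$mean_diameter))
    pc_stop_validation("`spec_a` must have the smaller mean diameter")
  if (spec_a$cv <= 0 || spec_b$cv <= 0)
    pc_stop_validation("both populations need `cv` > 0")
  f <- function(d)
    stats::dnorm(d, spec_a$mean_diameter,
                 spec_a$mean_diameter * spec_a$cv, log = TRUE) -
    stats::dnorm(d, spec_b$mean_diameter,
                 spec_b$mean_diameter * spec_b$cv, log = TRUE)
  lo <- spec_a$mean_diameter
  hi <- spec_b$mean_diameter
  if (f(lo) <= 0 || f(hi) >= 0)
    pc_stop("densities do not cross between the two means")
  stats::uniroot(f, c(lo, hi), tol = 1e-6)$root
}

#' Per-class histogram of matched peak amplitudes
#'
#' Uniform bins of width `bin_width` starting at 0, half-open `[lo, hi)`.
#'
#' @param pairs Matched pairs (the `pairs` element of a [match_events()]
#'   result) carrying `amplitude_mV` and `size_class`.
#' @param bin_width Bin width in mV, `> 0`.
#'
#' @return Data frame with columns `size_class`, `bin_lo`, `bin_hi`,
#'   `count`; all-zero (empty) for empty input.
#' @export
amplitude_histogram <- function(pairs, bin_width = 0.5) {
  check_scalar(bin_width, "bin_width", lower = 0, open_lower = TRUE)
  if (!is.data.frame(pairs) ||
      !all(c("amplitude_mV", "size_class") %in% names(pairs)))
    pc_stop_validation("`pairs` must have `amplitude_mV` and `size_class`")
  if (!nrow(pairs))
    return(data.frame(size_class = character(0), bin_lo = numeric(0),
                      bin_hi = numeric(0), count = integer(0)))
  n_bins <- floor(max(pairs$amplitude_mV) / bin_width) + 1L
  lo <- (seq_len(n_bins) - 1L) * bin_width
  out <- lapply(sort(unique(pairs$size_class)), function(cl) {
    a <- pairs$amplitude_mV[pairs$size_class == cl]
    bin <- findInterval(a, c(lo, n_bins * bin_width),
                        rightmost.closed = FALSE)
    data.frame(size_class = cl, bin_lo = lo, bin_hi = lo + bin_width,
               count = tabulate(bin, n_bins))
  })
  do.call(rbind, out)
}
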