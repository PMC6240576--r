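#' Peak detection settings for the electrical channel
#'
#' Defaults mirror the reference processing: a fixed 1 mV_rms threshold
#' (about three times the 0.307 mV_rms baseline noise), a 5 s moving-average
#' window for drift removal (at least ten times the longest default pulse
#' width, so pulses are not subtracted into themselves), and a 50 ms minimum
#' separation between peaks so one noisy pulse is not split in two.
#'
#' @param threshold Detection threshold in mV_rms, `> 0`.
#' @param moving_average_window Drift-removal window in seconds, `> 0`.
#' @param min_peak_gap Minimum gap between reported peaks in seconds, `>= 0`.
#'
#' @return An object of class `peak_detection_config`.
#' @export
peak_detection_config <- function(threshold = 1.0,
                                  moving_average_window = 5.0,
                                  min_peak_gap = 0.05) {
  check_scalar(threshold, "threshold", lower = 0, open_lower = TRUE)
  check_scalar(moving_average_window, "moving_average_window",
               lower = 0, open_lower = TRUE)
  check_scalar(min_peak_gap, "min_peak_gap", lower = 0)
  structure(list(threshold = as.numeric(threshold),
                 moving_average_window = as.numeric(moving_average_window),
                 min_peak_gap = as.numeric(min_peak_gap)),
            class = "peak_detection_config")
}

is_peak_detection_config <- function(x) inherits(x, "peak_detection_config")

#' Remove baseline drift with a centred moving average
#'
#' Subtracts from each sample the mean of a centred window of the given
#' length; at the edges the window shrinks (is truncated) to the available
#' samples. A constant baseline maps to zero everywhere and a linear ramp
#' maps to zero away from the edges.
#'
#' @param trace A [signal_trace()].
#' @param window Window length in seconds; must span at least 2 samples.
#'
#' @return A drift-removed [signal_trace()] of the same length.
#' @export
remove_drift <- function(trace, window = 5.0) {
  if (!is_signal_trace(trace))
    pc_stop_validation("`trace` must be a signal_trace")
  check_scalar(window, "window", lower = 0, open_lower = TRUE)
  fs <- trace$sample_rate
  if (window * fs < 2)
    pc_stop_validation("`window` must span at least 2 sample intervals")
  v <- trace$values
  n <- length(v)
  half <- floor(window * fs / 2)
  i <- seq_len(n)
  lo <- pmax(i - half, 1L)
  hi <- pmin(i + half, n)
  cs <- c(0, cumsum(v))
  avg <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  signal_trace(v - avg, fs, trace$start_time)
}

#' Estimate the baseline noise RMS
#'
#' Root mean square of the (drift-removed) samples, optionally excluding
#' pulse regions via a logical mask.
#'
#' @param trace A [signal_trace()], normally after [remove_drift()].
#' @param exclusion_mask Optional logical vector, `TRUE` for samples to
#'   exclude (e.g. around detected peaks). At least 100 samples must remain.
#'
#' @return Noise RMS in mV_rms.
#' @export
estimate_noise_rms <- function(trace, exclusion_mask = NULL) {
  if (!is_signal_trace(trace))
    pc_stop_validation("`trace` must be a signal_trace")
  v <- trace$values
  if (!is.null(exclusion_mask)) {
    if (!is.logical(exclusion_mask) || length(exclusion_mask) != length(v))
      pc_stop_validation("`exclusion_mask` must be logical, same length as trace")
    if (all(exclusion_mask))
      pc_stop("all samples are masked; cannot estimate noise")
    v <- v[!exclusion_mask]
  }
  if (length(v) < 100)
    pc_stop("need at least 100 unmasked samples to estimate noise")
  sqrt(mean(v^2))
}

# Exclusion mask covering +/- pad seconds around each peak.
peak_exclusion_mask <- function(trace, peaks, pad = 1.0) {
  tt <- trace_times(trace)
  mask <- rep(FALSE, length(tt))
  for (tp in peaks$time_s)
    mask <- mask | (abs(tt - tp) <= pad)
  mask
}

#' Detect pulses by fixed thresholding
#'
#' Contiguous runs of samples at or above the threshold form candidate
#' segments; segments separated by less than `min_peak_gap` are merged. Each
#' segment is reported as one peak at its maximum sample (ties broken toward
#' the earlier sample), with `time_s` the time of that sample and
#' `amplitude_mV` its value. The trace should already be drift-removed.
#'
#' @param trace A [signal_trace()].
#' @param cfg A [peak_detection_config()].
#'
#' @return Data frame with columns `time_s`, `amplitude_mV`, sorted by time.
#' @export
detect_peaks <- function(trace, cfg = peak_detection_config()) {
  if (!is_signal_trace(trace))
    pc_stop_validation("`trace` must be a signal_trace")
  if (!is_peak_detection_config(cfg))
    pc_stop_validation("`cfg` must be a peak_detection_config")
  v <- trace$values
  if (any(!is.finite(v)))
    pc_stop("trace contains non-finite samples")
  above <- v >= cfg$threshold
  if (!any(above)) return(empty_peaks())

  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- cbind(start = starts[r$values], end = ends[r$values])

  # merge segments whose gap is below min_peak_gap
  gap_samples <- cfg$min_peak_gap * trace$sample_rate
  if (nrow(seg) > 1L) {
    merged <- seg[1, , drop = FALSE]
    for (i in 2:nrow(seg)) {
      if (seg[i, "start"] - merged[nrow(merged), "end"] - 1L < gap_samples)
        merged[nrow(merged), "end"] <- seg[i, "end"]
      else
        merged <- rbind(merged, seg[i, , drop = FALSE])
    }
    seg <- merged
  }

  tt <- trace_times(trace)
  idx <- apply(seg, 1L, function(s) {
    rng <- s[["start"]]:s[["end"]]
    rng[which.max(v[rng])]
  })
  data.frame(time_s = tt[idx], amplitude_mV = v[idx])
}

empty_peaks <- function() data.frame(time_s = numeric(0),
                                     amplitude_mV = numeric(0))
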