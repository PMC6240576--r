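#' Construct a uniformly sampled signal trace
#'
#' @param values Numeric vector of demodulated amplitudes in mV_rms.
#' @param sample_rate Samples per second, `> 0`.
#' @param start_time Time of the first sample in seconds.
#'
#' @return An object of class `signal_trace`.
#' @export
signal_trace <- function(values, sample_rate, start_time = 0) {
  if (!is.numeric(values) || length(values) < 1L || any(!is.finite(values)))
    pc_stop_validation("`values` must be a non-empty finite numeric vector")
  check_scalar(sample_rate, "sample_rate", lower = 0, open_lower = TRUE)
  check_scalar(start_time, "start_time")
  structure(list(start_time = as.numeric(start_time),
                 sample_rate = as.numeric(sample_rate),
                 values = as.numeric(values)),
            class = "signal_trace")
}

is_signal_trace <- function(x) inherits(x, "signal_trace")

#' Sample times of a trace
#' @param trace A [signal_trace()].
#' @return Numeric vector of sample times in seconds.
#' @export
trace_times <- function(trace) {
  stopifnot(is_signal_trace(trace))
  trace$start_time + (seq_along(trace$values) - 1) / trace$sample_rate
}

#' @export
print.signal_trace <- function(x, ...) {
  cat(sprintf("<signal_trace> %d samples @ %.4g Hz (%.4g s), range [%.3g, %.3g] mV\n",
              length(x$values), x$sample_rate,
              length(x$values) / x$sample_rate,
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
as.data.frame.signal_trace <- function(x, ...) {
  data.frame(time_s = trace_times(x), amplitude_mV = x$values)
}

# One-pole recursive low-pass, y[i] = (1-a) y[i-1] + a x[i],
# a = dt / (tau + dt).  Discretisation of tau * y' + y = x.
lowpass_one_pole <- function(x, alpha) {
  as.numeric(stats::filter(alpha * x, 1 - alpha, method = "recursive"))
}

# Variance gain of the one-pole filter for white input: a / (2 - a).
# White noise injected upstream is pre-scaled by the inverse square root so
# the filtered baseline has the configured RMS.
lowpass_noise_scale <- function(alpha) sqrt((2 - alpha) / alpha)

#' Synthesize a demodulated impedance trace
#'
#' Each transit event contributes a Gaussian pulse centred at its crossing
#' time with peak `true_amplitude_mV` and full width at half maximum
#' `sensing_length / velocity`. The pulse train plus baseline noise is passed
#' through the single-pole output low-pass (time constant
#' `acq$filter_time_constant`; `0` bypasses it), so fast transits are
#' attenuated exactly as a band-limited lock-in output would attenuate them.
#' Noise is white Gaussian before the filter, pre-scaled so that the
#' *filtered* baseline RMS equals `acq$noise_rms`. Baseline drift (slow
#' sinusoid plus linear ramp) is added after the filter.
#'
#' @param events Event table from [generate_events()] (or equivalent).
#' @param acq An [acquisition_config()].
#' @param duration Trace duration in seconds; all events must lie inside
#'   `[0, duration]`.
#' @param seed Integer seed for the noise.
#'
#' @return A [signal_trace()] starting at `t = 0`.
#' @export
synthesize_trace <- function(events, acq, duration, seed) {
  check_events(events)
  if (!is_acquisition_config(acq))
    pc_stop_validation("`acq` must be an acquisition_config")
  check_scalar(duration, "duration", lower = 0, open_lower = TRUE)
  if (nrow(events) && (min(events$crossing_time_s) < 0 ||
                       max(events$crossing_time_s) > duration))
    pc_stop_validation("event crossing times must lie within [0, duration]")

  fs <- acq$sample_rate
  n <- max(1L, round(duration * fs))
  tt <- (seq_len(n) - 1) / fs
  x <- numeric(n)

  if (nrow(events)) {
    fwhm <- acq$sensing_length / events$velocity_um_s
    if (min(fwhm) * fs < 8)
      pc_stop("sample_rate too low: shortest pulse FWHM (",
              format(min(fwhm)), " s) spans fewer than 8 samples")
    sig <- fwhm / (2 * sqrt(2 * log(2)))
    for (i in seq_len(nrow(events))) {
      tc <- events$crossing_time_s[i]
      lo <- max(1L, floor((tc - 5 * sig[i]) * fs) + 1L)
      hi <- min(n, ceiling((tc + 5 * sig[i]) * fs) + 1L)
      idx <- lo:hi
      x[idx] <- x[idx] + events$true_amplitude_mV[i] *
        exp(-((tt[idx] - tc)^2) / (2 * sig[i]^2))
    }
  }

  noise <- if (acq$noise_rms > 0)
    with_seed(seed, stats::rnorm(n)) else numeric(n)

  if (acq$filter_time_constant > 0) {
    alpha <- (1 / fs) / (acq$filter_time_constant + 1 / fs)
    y <- lowpass_one_pole(x + acq$noise_rms * lowpass_noise_scale(alpha) * noise,
                          alpha)
  } else {
    y <- x + acq$noise_rms * noise
  }

  drift <- acq$drift_amplitude * sin(2 * pi * tt / acq$drift_period) +
    acq$drift_ramp * tt
  signal_trace(y + drift, fs, start_time = 0)
}
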