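#' Electrical acquisition settings
#'
#' Describes the demodulated (baseband) output of the lock-in measurement
#' chain. The carrier excitation itself is not simulated; `excitation_voltage`
#' and `excitation_frequency` are metadata. The lock-in output filter is
#' modelled as a single-pole low-pass with time constant
#' `filter_time_constant`; `sensing_length` is the effective length of the
#' sensing zone between the coplanar electrodes and sets the transit pulse
#' width (FWHM = sensing_length / velocity). Baseline drift is a slow
#' sinusoid (`drift_amplitude`, `drift_period`) plus a linear ramp
#' (`drift_ramp`).
#'
#' @param sample_rate Samples per second of the demodulated trace.
#' @param gain Total trans-impedance amplification in V/A (default 100 kV/A).
#' @param excitation_voltage Excitation amplitude in V_RMS (metadata).
#' @param excitation_frequency Excitation frequency in Hz (metadata).
#' @param noise_rms RMS of the baseline noise at the filter output, in
#'   mV_rms. Noise is injected ahead of the output filter and scaled so the
#'   filtered baseline has exactly this RMS.
#' @param filter_time_constant Output low-pass time constant in seconds;
#'   `0` disables filtering.
#' @param sensing_length Effective sensing-zone length in micrometres.
#' @param drift_amplitude Amplitude of the sinusoidal baseline drift in mV.
#' @param drift_period Period of the sinusoidal drift in seconds.
#' @param drift_ramp Linear baseline ramp in mV per second.
#'
#' @return An object of class `acquisition_config`.
#' @export
acquisition_config <- function(sample_rate = 1000,
                               gain = 1e5,
                               excitation_voltage = 0.3,
                               excitation_frequency = 90e3,
                               noise_rms = 0.307,
                               filter_time_constant = 0.030,
                               sensing_length = 25,
                               drift_amplitude = 0.5,
                               drift_period = 30,
                               drift_ramp = 0.2 / 60) {
  check_scalar(sample_rate, "sample_rate", lower = 0, open_lower = TRUE)
  check_scalar(gain, "gain", lower = 0, open_lower = TRUE)
  check_scalar(excitation_voltage, "excitation_voltage", lower = 0)
  check_scalar(excitation_frequency, "excitation_frequency", lower = 0)
  check_scalar(noise_rms, "noise_rms", lower = 0)
  check_scalar(filter_time_constant, "filter_time_constant", lower = 0)
  check_scalar(sensing_length, "sensing_length", lower = 0, open_lower = TRUE)
  check_scalar(drift_amplitude, "drift_amplitude", lower = 0)
  check_scalar(drift_period, "drift_period", lower = 0, open_lower = TRUE)
  check_scalar(drift_ramp, "drift_ramp")
  structure(
    list(sample_rate = as.numeric(sample_rate),
         gain = as.numeric(gain),
         excitation_voltage = as.numeric(excitation_voltage),
         excitation_frequency = as.numeric(excitation_frequency),
         noise_rms = as.numeric(noise_rms),
         filter_time_constant = as.numeric(filter_time_constant),
         sensing_length = as.numeric(sensing_length),
         drift_amplitude = as.numeric(drift_amplitude),
         drift_period = as.numeric(drift_period),
         drift_ramp = as.numeric(drift_ramp)),
    class = "acquisition_config"
  )
}

#' @export
print.acquisition_config <- function(x, ...) {
  cat(sprintf(paste0("<acquisition_config> fs %.5g Hz, gain %.3g V/A, ",
                     "noise %.3g mV_rms, tau %.3g s, sensing %.3g um\n"),
              x$sample_rate, x$gain, x$noise_rms,
              x$filter_time_constant, x$sensing_length))
  invisible(x)
}

is_acquisition_config <- function(x) inherits(x, "acquisition_config")
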