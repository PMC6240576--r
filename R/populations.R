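#' Describe a bead population
#'
#' A bead population is characterised by the manufacturer's nominal diameter
#' and coefficient of variation (CV); diameters are modelled as a normal
#' distribution `Normal(mean, mean * cv)` truncated at zero. `event_rate`
#' gives the mean number of transit events per second when the population is
#' pumped through the sensing channel.
#'
#' @param label Short name used in reports (e.g. `"6um"`).
#' @param mean_diameter Nominal diameter in micrometres, `> 0`.
#' @param cv Coefficient of variation (sd / mean) as a fraction in `[0, 1)`.
#' @param event_rate Mean transit events per second, `>= 0`.
#'
#' @return An object of class `bead_population`.
#' @examples
#' bead_population("6um", 6, 0.07)
#' bead_population("11um", 11, 0.18)
#' @export
bead_population <- function(label, mean_diameter, cv, event_rate = 0.5) {
  check_string(label, "label")
  check_scalar(mean_diameter, "mean_diameter", lower = 0, open_lower = TRUE)
  check_scalar(cv, "cv", lower = 0, upper = 1, open_upper = TRUE)
  check_scalar(event_rate, "event_rate", lower = 0)
  structure(
    list(label = label, mean_diameter = as.numeric(mean_diameter),
         cv = as.numeric(cv), event_rate = as.numeric(event_rate)),
    class = "bead_population"
  )
}

#' @export
print.bead_population <- function(x, ...) {
  cat(sprintf("<bead_population '%s'> mean %.3g um, CV %.1f%%, rate %.3g /s\n",
              x$label, x$mean_diameter, 100 * x$cv, x$event_rate))
  invisible(x)
}

is_bead_population <- function(x) inherits(x, "bead_population")

# Normal draws truncated at zero; non-positive values are redrawn.
r_truncnorm_pos <- function(n, mean, sd) {
  d <- stats::rnorm(n, mean, sd)
  while (any(bad <- d <= 0))
    d[bad] <- stats::rnorm(sum(bad), mean, sd)
  d
}

#' Sample bead diameters from a population
#'
#' Draws from `Normal(mean_diameter, mean_diameter * cv)` truncated at zero
#' (non-positive draws are redrawn). With `cv = 0` every draw equals the
#' nominal diameter.
#'
#' @param spec A [bead_population()].
#' @param n Number of diameters to draw, `>= 0`.
#' @param seed Integer seed; draws are reproducible for a fixed seed.
#'
#' @return Numeric vector of `n` diameters in micrometres.
#' @export
sample_diameters <- function(spec, n, seed) {
  if (!is_bead_population(spec))
    pc_stop_validation("`spec` must be a bead_population")
  check_scalar(n, "n", lower = 0, integer = TRUE)
  with_seed(seed, r_truncnorm_pos(n, spec$mean_diameter,
                                  spec$mean_diameter * spec$cv))
}

#' Amplitude calibration constant
#'
#' Pulse amplitude in resistive pulse sensing scales with particle volume,
#' i.e. with diameter cubed. The default calibration anchors a 6 um bead at
#' 1.6 mV_rms of demodulated output, the average amplitude observed for that
#' bead size on the reference hardware, giving `k = 1.6 / 6^3` mV per um^3.
#'
#' @return The default volume-to-amplitude constant in mV per cubic
#'   micrometre.
#' @export
default_calibration_k <- function() 1.6 / 6^3

#' Ideal (unattenuated) pulse amplitude for a bead diameter
#'
#' Implements the volumetric amplitude law `A = k * d^3`: the pulse height a
#' bead would produce with no low-pass attenuation and no noise.
#'
#' @param diameter Bead diameter(s) in micrometres, `>= 0`.
#' @param calibration_k Volume-to-amplitude constant in mV/um^3.
#'
#' @return Amplitude(s) in mV_rms.
#' @examples
#' ideal_amplitude(6)   # 1.6 mV_rms by calibration
#' ideal_amplitude(11)  # about 9.86 mV_rms
#' @export
ideal_amplitude <- function(diameter, calibration_k = default_calibration_k()) {
  if (!is.numeric(diameter) || any(!is.finite(diameter)))
    pc_stop_validation("`diameter` must be finite numeric")
  if (any(diameter < 0))
    pc_stop_validation("`diameter` must be non-negative")
  check_scalar(calibration_k, "calibration_k", lower = 0, open_lower = TRUE)
  calibration_k * diameter^3
}
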