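#' Generate ground-truth transit events
#'
#' With the default `arrivals = "poisson"` each population contributes a
#' homogeneous Poisson process of bead arrivals over `[0, duration]`.
#' `arrivals = "spaced"` instead lays the expected number of events
#' (`round(event_rate * duration)` per population) on an even time grid with
#' +/-25% jitter and randomly interleaved population labels: a dilute,
#' well-separated transit schedule for calibration runs, where pulses never
#' overlap in the electrical channel. Bead diameters are drawn from the
#' population's truncated-normal law, every bead transits at the common run
#' velocity, and the ideal (unattenuated) pulse amplitude follows the
#' volumetric law `k * d^3`.
#'
#' @param specs A [bead_population()] or a list of them; an empty list gives
#'   an empty event table.
#' @param duration Run duration in seconds, `> 0`.
#' @param velocity Common bead transit velocity in um/s, `> 0`.
#' @param calibration_k Volume-to-amplitude constant in mV/um^3.
#' @param seed Integer seed.
#' @param arrivals Arrival schedule, `"poisson"` (default) or `"spaced"`.
#'
#' @return A data frame of class `transit_events`, sorted by crossing time,
#'   with columns `bead_id`, `label`, `diameter_um`, `velocity_um_s`,
#'   `crossing_time_s`, `true_amplitude_mV`.
#' @export
generate_events <- function(specs, duration, velocity,
                            calibration_k = default_calibration_k(), seed,
                            arrivals = c("poisson", "spaced")) {
  if (is_bead_population(specs)) specs <- list(specs)
  if (!is.list(specs) || !all(vapply(specs, is_bead_population, logical(1))))
    pc_stop_validation("`specs` must be bead_population objects")
  check_scalar(duration, "duration", lower = 0, open_lower = TRUE)
  check_scalar(velocity, "velocity", lower = 0, open_lower = TRUE)
  arrivals <- match.arg(arrivals)

  ev <- with_seed(seed, {
    if (arrivals == "poisson") {
      parts <- lapply(specs, function(sp) {
        n <- stats::rpois(1L, sp$event_rate * duration)
        data.frame(label = rep(sp$label, n),
                   diameter_um = r_truncnorm_pos(n, sp$mean_diameter,
                                                 sp$mean_diameter * sp$cv),
                   crossing_time_s = stats::runif(n, 0, duration),
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, c(parts, list(empty_event_part())))
    } else {
      counts <- vapply(specs, function(sp)
        as.integer(round(sp$event_rate * duration)), integer(1))
      n <- sum(counts)
      labels <- unlist(mapply(function(sp, k) rep(sp$label, k),
                              specs, counts, SIMPLIFY = FALSE))
      diams <- unlist(mapply(function(sp, k)
        r_truncnorm_pos(k, sp$mean_diameter, sp$mean_diameter * sp$cv),
        specs, counts, SIMPLIFY = FALSE))
      perm <- if (n) sample.int(n) else integer(0)
      spacing <- duration / max(1L, n)
      data.frame(label = as.character(labels)[perm],
                 diameter_um = as.numeric(diams)[perm],
                 crossing_time_s = (seq_len(n) - 0.5) * spacing +
                   stats::runif(n, -0.25, 0.25) * spacing,
                 stringsAsFactors = FALSE)
    }
  })
  ev <- ev[order(ev$crossing_time_s), , drop = FALSE]
  out <- data.frame(bead_id = seq_len(nrow(ev)),
                    label = ev$label,
                    diameter_um = ev$diameter_um,
                    velocity_um_s = rep(as.numeric(velocity), nrow(ev)),
                    crossing_time_s = ev$crossing_time_s,
                    true_amplitude_mV = ideal_amplitude(ev$diameter_um,
                                                        calibration_k),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("transit_events", "data.frame")
  out
}

empty_event_part <- function() {
  data.frame(label = character(0), diameter_um = numeric(0),
             crossing_time_s = numeric(0), stringsAsFactors = FALSE)
}

# Validate a user-supplied or generated event table.
check_events <- function(events) {
  need <- c("bead_id", "label", "diameter_um", "velocity_um_s",
            "crossing_time_s", "true_amplitude_mV")
  if (!is.data.frame(events) || !all(need %in% names(events)))
    pc_stop_validation("`events` must have columns ",
                       paste(need, collapse = ", "))
  if (nrow(events)) {
    if (any(events$diameter_um <= 0) || any(events$velocity_um_s <= 0) ||
        any(events$true_amplitude_mV < 0))
      pc_stop_validation("invalid event table: diameters/velocities must be ",
                         "positive and amplitudes non-negative")
    if (is.unsorted(events$crossing_time_s))
      pc_stop_validation("events must be sorted by `crossing_time_s`")
  }
  invisible(events)
}
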