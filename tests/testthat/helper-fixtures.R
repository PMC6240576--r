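# Shared fixture builders. All fixtures are generated in code at test time.

# Acquisition with noise and drift switched off.
acq_quiet <- function(...) {
  acquisition_config(noise_rms = 0, drift_amplitude = 0, drift_ramp = 0, ...)
}

# Hand-built event table (already sorted by crossing time).
make_events <- function(crossing_times, diameters, velocity,
                        labels = "bead",
                        calibration_k = default_calibration_k()) {
  ord <- order(crossing_times)
  data.frame(bead_id = seq_along(crossing_times),
             label = rep_len(labels, length(crossing_times))[ord],
             diameter_um = rep_len(diameters, length(crossing_times))[ord],
             velocity_um_s = rep(velocity, length(crossing_times)),
             crossing_time_s = crossing_times[ord],
             true_amplitude_mV =
               ideal_amplitude(rep_len(diameters,
                                       length(crossing_times))[ord],
                               calibration_k),
             stringsAsFactors = FALSE)
}

# A frame with disks drawn at given 0-based centres/radii.
make_disk_frame <- function(centres_x, centres_y, radii,
                            width = 64, height = 48,
                            background = 200, level = 60) {
  frame <- matrix(background, height, width)
  for (i in seq_along(centres_x)) {
    for (col in 1:width) {
      for (row in 1:height) {
        if ((col - 1 - centres_x[i])^2 + (row - 1 - centres_y[i])^2 <=
            radii[i]^2)
          frame[row, col] <- level
      }
    }
  }
  frame
}

default_6um <- function(rate = 0.5) bead_population("6um", 6, 0.07, rate)
default_11um <- function(rate = 0.5) bead_population("11um", 11, 0.18, rate)

tmp_path <- function(ext = "") tempfile(fileext = ext)

tmp_dir <- function() {
  d <- tempfile()
  dir.create(d)
  d
}
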