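Package: pulsecount
Title: Simulation and Analysis of Impedance-Based Particle Counting Experiments
Version: 0.1.0
Authors@R:
    person("Tobias", "Vermeer", email = "t.vermeer@posteo.net",
           role = c("aut", "cre"))
Description: Tools for microfluidic resistive pulse sensing (AC Coulter
    counter) experiments in which transiting particles are recorded
    simultaneously as demodulated impedance pulses and as bright-field
    video. Provides a ground-truthed synthetic data generator (bead size
    populations, Poisson transit events, lock-in style traces with drift
    and band-limited noise, rasterized frame stacks), moving-average
    baseline removal and threshold peak detection for the electrical
    channel, per-frame blob segmentation with pixel-area sizing and
    nearest-neighbour trajectory linking for the video channel, time-window
    matching of video crossings to electrical peaks, and per-size-class
    detection-rate and false-positive reporting, plus a command-line
    interface covering the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
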