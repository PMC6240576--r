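# Run configuration: a single JSON document with `populations`,
# `acquisition`, `video`, `detection`, `match` and `run` sections plus a
# `seed` and an `output_dir`. Every key maps to a constructor argument of
# the corresponding config object; unknown keys are rejected.

#' Default bead populations
#'
#' The two reference populations: nominal 6 um beads with 7% CV and nominal
#' 11 um beads with 18% CV, each at 0.5 transit events per second.
#'
#' @return List of two [bead_population()]s.
#' @export
default_populations <- function() {
  list(bead_population("6um", 6, 0.07, 0.5),
       bead_population("11um", 11, 0.18, 0.5))
}

run_section <- function(duration = 60, velocity = 110, write_frames = TRUE,
                        calibration_k = default_calibration_k()) {
  check_scalar(duration, "duration", lower = 0)
  check_scalar(velocity, "velocity", lower = 0, open_lower = TRUE)
  check_flag(write_frames, "write_frames")
  check_scalar(calibration_k, "calibration_k", lower = 0, open_lower = TRUE)
  list(duration = as.numeric(duration), velocity = as.numeric(velocity),
       write_frames = write_frames, calibration_k = as.numeric(calibration_k))
}

#' Default run configuration
#'
#' All-defaults configuration: the two reference bead populations, the
#' reference acquisition chain (1 mV threshold, 100 kV/A gain, 0.307 mV_rms
#' noise), a 60 s mixed run at 110 um/s.
#'
#' @return An object of class `run_config`.
#' @export
default_config <- function() {
  structure(
    list(populations = default_populations(),
         acquisition = acquisition_config(),
         video = video_config(),
         detection = peak_detection_config(),
         match = match_config(),
         run = run_section(),
         seed = 1L,
         output_dir = "pulsecount-run"),
    class = "run_config")
}

is_run_config <- function(x) inherits(x, "run_config")

apply_section <- function(ctor, given, section) {
  allowed <- names(formals(ctor))
  unknown <- setdiff(names(given), allowed)
  if (length(unknown))
    pc_stop_validation("unknown key", if (length(unknown) > 1) "s", " in `",
                       section, "`: ", paste0("`", unknown, "`",
                                              collapse = ", "))
  do.call(ctor, given)
}

build_config <- function(lst) {
  if (!is.list(lst)) pc_stop_validation("configuration must be a JSON object")
  allowed <- c("populations", "acquisition", "video", "detection", "match",
               "run", "seed", "output_dir")
  unknown <- setdiff(names(lst), allowed)
  if (length(unknown))
    pc_stop_validation("unknown top-level key",
                       if (length(unknown) > 1) "s", ": ",
                       paste0("`", unknown, "`", collapse = ", "))
  pops <- if (is.null(lst$populations)) default_populations()
  else lapply(lst$populations, function(p)
    apply_section(bead_population, p, "populations"))
  cfg <- structure(
    list(populations = pops,
         acquisition = apply_section(acquisition_config,
                                     lst$acquisition %||% list(),
                                     "acquisition"),
         video = apply_section(video_config, lst$video %||% list(), "video"),
         detection = apply_section(peak_detection_config,
                                   lst$detection %||% list(), "detection"),
         match = apply_section(match_config, lst$match %||% list(), "match"),
         run = apply_section(run_section, lst$run %||% list(), "run"),
         seed = lst$seed %||% 1L,
         output_dir = lst$output_dir %||% "pulsecount-run"),
    class = "run_config")
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L ||
      cfg$seed != round(cfg$seed))
    pc_stop_validation("`seed` must be a single integer")
  cfg$seed <- as.integer(cfg$seed)
  check_string(cfg$output_dir, "output_dir")
  cfg
}

#' Load and validate a run configuration from JSON
#'
#' Missing sections and keys fall back to documented defaults; unknown keys
#' raise a validation error naming the offending key; field ranges are
#' checked by the section constructors. An empty JSON object yields the
#' all-defaults configuration.
#'
#' @param path Path to a JSON configuration file.
#' @return An object of class `run_config`.
#' @seealso [save_config()], [default_config()]
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    pc_stop_validation("configuration file not found: ", path)
  lst <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e)
                    pc_stop_validation("cannot parse JSON: ",
                                       conditionMessage(e)))
  build_config(lst)
}

#' Save a run configuration as JSON
#'
#' `load_config(save_config(cfg, path))` reproduces `cfg` exactly.
#'
#' @param config A `run_config`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
save_config <- function(config, path) {
  if (!is_run_config(config))
    pc_stop_validation("`config` must be a run_config")
  lst <- list(populations = lapply(config$populations, unclass),
              acquisition = unclass(config$acquisition),
              video = unclass(config$video),
              detection = unclass(config$detection),
              match = unclass(config$match),
              run = config$run,
              seed = config$seed,
              output_dir = config$output_dir)
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Preset configurations mirroring the three reference experiments
#'
#' `"6um"`: 6 um solution at 110 um/s; `"11um"`: 11 um solution at
#' 344 um/s; `"mixed"`: both populations 1:1 at 289 um/s.
#'
#' @param preset One of `"6um"`, `"11um"`, `"mixed"`.
#' @param duration Run duration in seconds.
#' @return A `run_config`.
#' @export
preset_config <- function(preset = c("mixed", "6um", "11um"), duration = 60) {
  preset <- match.arg(preset)
  cfg <- default_config()
  cfg$run$duration <- duration
  pops <- default_populations()
  if (preset == "6um") {
    cfg$populations <- pops[1]
    cfg$populations[[1]]$event_rate <- 1.0
    cfg$run$velocity <- 110
  } else if (preset == "11um") {
    cfg$populations <- pops[2]
    cfg$run$velocity <- 344
  } else {
    cfg$run$velocity <- 289
  }
  cfg
}
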