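#' Video acquisition settings
#'
#' Geometry and intensities of the simulated bright-field recording: dark
#' beads on a light background, moving in +x along the channel centreline.
#' `electrode_x` is the position of the electrode pair (the point whose
#' crossing time is compared with the electrical peak) in micrometres from
#' the left frame edge.
#'
#' @param frame_rate Frames per second.
#' @param frame_width,frame_height Frame size in pixels.
#' @param pixel_scale Micrometres per pixel.
#' @param electrode_x Electrode position in micrometres; must lie inside the
#'   imaged field.
#' @param background_intensity,bead_intensity 8-bit grey levels (0-255);
#'   beads must be darker than the background.
#'
#' @return An object of class `video_config`.
#' @export
video_config <- function(frame_rate = 60,
                         frame_width = 256,
                         frame_height = 48,
                         pixel_scale = 1,
                         electrode_x = 128,
                         background_intensity = 200,
                         bead_intensity = 60) {
  check_scalar(frame_rate, "frame_rate", lower = 0, open_lower = TRUE)
  check_scalar(frame_width, "frame_width", lower = 2, integer = TRUE)
  check_scalar(frame_height, "frame_height", lower = 2, integer = TRUE)
  check_scalar(pixel_scale, "pixel_scale", lower = 0, open_lower = TRUE)
  check_scalar(electrode_x, "electrode_x")
  check_scalar(background_intensity, "background_intensity", 0, 255)
  check_scalar(bead_intensity, "bead_intensity", 0, 255)
  if (bead_intensity >= background_intensity)
    pc_stop_validation("`bead_intensity` must be below `background_intensity`",
                       " (dark beads on a bright field)")
  if (electrode_x < 0 || electrode_x > (frame_width - 1) * pixel_scale)
    pc_stop_validation("`electrode_x` must lie inside the imaged field")
  structure(
    list(frame_rate = as.numeric(frame_rate),
         frame_width = as.integer(frame_width),
         frame_height = as.integer(frame_height),
         pixel_scale = as.numeric(pixel_scale),
         electrode_x = as.numeric(electrode_x),
         background_intensity = as.numeric(background_intensity),
         bead_intensity = as.numeric(bead_intensity)),
    class = "video_config"
  )
}

is_video_config <- function(x) inherits(x, "video_config")

#' @export
print.video_config <- function(x, ...) {
  cat(sprintf("<video_config> %dx%d px @ %.3g fps, %.3g um/px, electrode at %.3g um\n",
              x$frame_width, x$frame_height, x$frame_rate, x$pixel_scale,
              x$electrode_x))
  invisible(x)
}

# Default segmentation threshold: halfway between bead and background levels.
default_intensity_threshold <- function(vconf) {
  (vconf$background_intensity + vconf$bead_intensity) / 2
}

# Binary disk rasterization: pixel (row i, col j), 1-based, has 0-based
# centre coordinates x = j - 1, y = i - 1; a pixel is foreground iff its
# centre lies within the disk. No anti-aliasing, so areas are reproducible.
draw_disk <- function(frame, cx, cy, r, level) {
  h <- nrow(frame); w <- ncol(frame)
  cols <- max(1L, floor(cx - r) + 1L):min(w, ceiling(cx + r) + 1L)
  rows <- max(1L, floor(cy - r) + 1L):min(h, ceiling(cy + r) + 1L)
  if (!length(cols) || !length(rows)) return(frame)
  dx2 <- ((cols - 1) - cx)^2
  dy2 <- ((rows - 1) - cy)^2
  mask <- outer(dy2, dx2, `+`) <= r^2
  if (any(mask)) {
    sub <- frame[rows, cols, drop = FALSE]
    sub[mask] <- level
    frame[rows, cols] <- sub
  }
  frame
}

# Beads visible in the frame at time t: 0-based pixel x positions.
beads_in_view <- function(events, vconf, t) {
  x_um <- (t - events$crossing_time_s) * events$velocity_um_s +
    vconf$electrode_x
  x_px <- x_um / vconf$pixel_scale
  r_px <- events$diameter_um / 2 / vconf$pixel_scale
  keep <- x_px + r_px >= 0 & x_px - r_px <= vconf$frame_width - 1
  data.frame(bead_id = events$bead_id[keep],
             diameter_um = events$diameter_um[keep],
             x_px = x_px[keep],
             r_px = r_px[keep])
}

render_one_frame <- function(events, vconf, t) {
  frame <- matrix(as.integer(vconf$background_intensity),
                  vconf$frame_height, vconf$frame_width)
  vis <- beads_in_view(events, vconf, t)
  y_px <- (vconf$frame_height - 1) / 2
  for (i in seq_len(nrow(vis)))
    frame <- draw_disk(frame, vis$x_px[i], y_px, vis$r_px[i],
                       as.integer(vconf$bead_intensity))
  frame
}

#' Render a synthetic frame stack with ground truth
#'
#' Draws each in-view bead as a filled binary disk (radius `diameter/2`
#' converted to pixels, no anti-aliasing) on the channel centreline at
#' `x = (t - crossing_time) * velocity + electrode_x`. Frame `k` (0-based) is
#' exposed instantaneously at `t = k / frame_rate`.
#'
#' @param events Event table from [generate_events()].
#' @param vconf A [video_config()].
#' @param duration Recording duration in seconds.
#'
#' @return A list with `frames` (list of integer matrices, `height x width`,
#'   grey levels 0-255) and `truth` (data frame: `frame`, `time_s`,
#'   `bead_id`, `x_px`, `y_px`, `diameter_um`, `sub_resolution`). Beads whose
#'   diameter spans fewer than 2 pixels are flagged `sub_resolution` with a
#'   one-time warning.
#' @export
render_frames <- function(events, vconf, duration) {
  check_events(events)
  if (!is_video_config(vconf))
    pc_stop_validation("`vconf` must be a video_config")
  check_scalar(duration, "duration", lower = 0, open_lower = TRUE)

  n_frames <- max(1L, round(duration * vconf$frame_rate))
  y_px <- (vconf$frame_height - 1) / 2
  frames <- vector("list", n_frames)
  truth <- vector("list", n_frames)
  subres_seen <- FALSE
  for (k in seq_len(n_frames)) {
    t <- (k - 1) / vconf$frame_rate
    frames[[k]] <- render_one_frame(events, vconf, t)
    vis <- beads_in_view(events, vconf, t)
    if (nrow(vis)) {
      sub <- vis$diameter_um / vconf$pixel_scale < 2
      if (any(sub)) subres_seen <- TRUE
      truth[[k]] <- data.frame(frame = k - 1L, time_s = t,
                               bead_id = vis$bead_id, x_px = vis$x_px,
                               y_px = y_px, diameter_um = vis$diameter_um,
                               sub_resolution = sub)
    }
  }
  if (subres_seen)
    warning("some beads are below 2 px at the configured pixel_scale",
            call. = FALSE)
  truth <- do.call(rbind, c(truth[!vapply(truth, is.null, logical(1))],
                            list(empty_truth())))
  rownames(truth) <- NULL
  list(frames = frames, truth = truth)
}

empty_truth <- function() {
  data.frame(frame = integer(0), time_s = numeric(0), bead_id = integer(0),
             x_px = numeric(0), y_px = numeric(0), diameter_um = numeric(0),
             sub_resolution = logical(0))
}
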