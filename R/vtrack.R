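# Video-channel processing: per-frame blob segmentation, pixel-area sizing,
# greedy nearest-neighbour trajectory linking, velocity and electrode
# crossing-time estimation.

# 8-connected component labelling of a logical matrix by iterated minimum
# propagation over foreground pixels only. Returns the linear indices of
# foreground pixels and a compact component id per pixel.
label_components8 <- function(fg) {
  idx <- which(fg)
  npx <- length(idx)
  if (!npx)
    return(list(idx = integer(0), comp = integer(0)))
  h <- nrow(fg)
  len <- length(fg)
  pos <- integer(len)
  pos[idx] <- seq_len(npx)
  ri <- ((idx - 1L) %% h) + 1L
  offs <- c(-1L, 1L, -h, h, -h - 1L, -h + 1L, h - 1L, h + 1L)
  drow <- c(-1L, 1L, 0L, 0L, -1L, 1L, -1L, 1L)
  # precompute, per offset, which pixels have a foreground neighbour and
  # that neighbour's position in the pixel list
  src <- vector("list", 8L)
  tgt <- vector("list", 8L)
  for (k in 1:8) {
    nidx <- idx + offs[k]
    nr <- ri + drow[k]
    ok <- nidx >= 1L & nidx <= len & nr >= 1L & nr <= h
    p <- integer(npx)
    p[ok] <- pos[nidx[ok]]
    src[[k]] <- which(p > 0L)
    tgt[[k]] <- p[src[[k]]]
  }
  lab <- seq_len(npx)
  repeat {
    m <- lab
    for (k in 1:8)
      m[src[[k]]] <- pmin(m[src[[k]]], lab[tgt[[k]]])
    # pointer doubling for logarithmic convergence
    m <- pmin(m, m[m])
    m <- pmin(m, m[m])
    if (identical(m, lab)) break
    lab <- m
  }
  list(idx = idx, comp = match(lab, unique(lab)))
}

# Fast core: returns a matrix with columns (centroid_x, centroid_y,
# pixel_area); centroids are 0-based pixel coordinates.
segment_core <- function(frame, intensity_threshold, min_area) {
  lc <- label_components8(frame < intensity_threshold)
  if (!length(lc$idx))
    return(matrix(numeric(0), 0L, 3L))
  h <- nrow(frame)
  x <- (lc$idx - 1L) %/% h      # 0-based column
  y <- (lc$idx - 1L) %% h       # 0-based row
  area <- tabulate(lc$comp)
  cx <- rowsum(as.numeric(x), lc$comp)[, 1] / area
  cy <- rowsum(as.numeric(y), lc$comp)[, 1] / area
  keep <- area >= min_area
  cbind(cx[keep], cy[keep], area[keep])
}

#' Segment beads in one frame
#'
#' Pixels strictly below `intensity_threshold` (dark beads on a bright
#' field) form the foreground; 8-connected components with at least
#' `min_area` pixels become detections. Centroids are unweighted pixel means
#' in 0-based pixel coordinates; the estimated diameter is that of the
#' equivalent circle, `2 * pixel_scale * sqrt(area / pi)`.
#'
#' @param frame Numeric/integer matrix (`height x width`), 8-bit grey levels.
#' @param intensity_threshold Foreground threshold (default 128).
#' @param min_area Minimum component area in pixels (default 4).
#' @param pixel_scale Micrometres per pixel.
#' @param frame_index 0-based frame number recorded in the output.
#' @param frame_rate Frames per second, used to timestamp the detection.
#'
#' @return Data frame with columns `frame_index`, `time_s`, `centroid_x`,
#'   `centroid_y`, `pixel_area`, `est_diameter_um`; empty for a uniform
#'   frame.
#' @export
segment_frame <- function(frame, intensity_threshold = 128, min_area = 4,
                          pixel_scale = 1, frame_index = 0, frame_rate = 60) {
  if (!is.matrix(frame) || !is.numeric(frame))
    pc_stop_validation("`frame` must be a numeric matrix")
  check_scalar(intensity_threshold, "intensity_threshold", 0, 255)
  check_scalar(min_area, "min_area", lower = 0)
  check_scalar(pixel_scale, "pixel_scale", lower = 0, open_lower = TRUE)
  m <- segment_core(frame, intensity_threshold, min_area)
  data.frame(frame_index = rep(as.integer(frame_index), nrow(m)),
             time_s = rep(frame_index / frame_rate, nrow(m)),
             centroid_x = m[, 1], centroid_y = m[, 2],
             pixel_area = m[, 3],
             est_diameter_um = 2 * pixel_scale * sqrt(m[, 3] / pi))
}

#' Link per-frame detections into trajectories
#'
#' Greedy nearest-neighbour frame-to-frame assignment: detections in frame
#' `f` are paired with track heads from frame `f - 1` in ascending centroid
#' distance; pairs farther apart than `max_step` pixels start new tracks.
#' Every detection belongs to exactly one track.
#'
#' @param detections Data frame with at least `frame_index`, `centroid_x`,
#'   `centroid_y` (as produced by [segment_frame()] over a stack).
#' @param max_step Maximum centroid displacement per frame, in pixels.
#'
#' @return The input data frame with a `track_id` column appended.
#' @export
link_tracks <- function(detections, max_step) {
  need <- c("frame_index", "centroid_x", "centroid_y")
  if (!is.data.frame(detections) || !all(need %in% names(detections)))
    pc_stop_validation("`detections` must have columns ",
                       paste(need, collapse = ", "))
  check_scalar(max_step, "max_step", lower = 0, open_lower = TRUE)
  n <- nrow(detections)
  track_id <- integer(n)
  if (n) {
    ord <- order(detections$frame_index)
    by_frame <- split(ord, detections$frame_index[ord])
    next_id <- 0L
    prev_rows <- integer(0)
    prev_frame <- NA_integer_
    for (fi in names(by_frame)) {
      rows <- by_frame[[fi]]
      f <- detections$frame_index[rows[1L]]
      active <- if (!is.na(prev_frame) && f == prev_frame + 1L)
        prev_rows else integer(0)
      assigned <- rep(FALSE, length(rows))
      if (length(active)) {
        d <- outer(detections$centroid_x[rows], detections$centroid_x[active],
                   `-`)^2 +
          outer(detections$centroid_y[rows], detections$centroid_y[active],
                `-`)^2
        d <- sqrt(d)
        used_prev <- rep(FALSE, length(active))
        repeat {
          d[assigned, ] <- Inf
          d[, used_prev] <- Inf
          if (!length(d) || min(d) > max_step) break
          w <- arrayInd(which.min(d), dim(d))
          i <- w[1L]; j <- w[2L]
          track_id[rows[i]] <- track_id[active[j]]
          assigned[i] <- TRUE
          used_prev[j] <- TRUE
        }
      }
      for (i in which(!assigned)) {
        next_id <- next_id + 1L
        track_id[rows[i]] <- next_id
      }
      prev_rows <- rows
      prev_frame <- f
    }
  }
  detections$track_id <- track_id
  detections
}

#' Estimate a track's flow velocity
#'
#' Median of the per-frame x-displacements, scaled to physical units. The
#' median makes the estimate robust to centroid quantisation at the frame
#' edges. The sign follows the flow direction (+x); reversing the frame
#' order flips the sign.
#'
#' @param track Detections of a single track, with `frame_index` and
#'   `centroid_x`; at least 2 detections.
#' @param frame_rate Frames per second.
#' @param pixel_scale Micrometres per pixel.
#'
#' @return Velocity in um/s.
#' @export
estimate_velocity <- function(track, frame_rate = 60, pixel_scale = 1) {
  if (!is.data.frame(track) || nrow(track) < 2)
    pc_stop("a track needs at least 2 detections to estimate velocity")
  dx <- diff(track$centroid_x) / diff(track$frame_index)
  stats::median(dx) * frame_rate * pixel_scale
}

#' Interpolate the electrode crossing time of a track
#'
#' Linear interpolation of time versus centroid x at `x = electrode_x`. If
#' the track does not bracket the electrode but its nearest point lies
#' within one frame-step of it, the crossing is linearly extrapolated from
#' the nearest pair of detections; otherwise `NA` is returned (no crossing).
#'
#' @param track Detections of a single track, ordered by `frame_index`, with
#'   `time_s` and `centroid_x`.
#' @param electrode_x Electrode position in micrometres.
#' @param pixel_scale Micrometres per pixel.
#'
#' @return Crossing time in seconds, or `NA_real_`.
#' @export
crossing_time <- function(track, electrode_x, pixel_scale = 1) {
  if (!is.data.frame(track) || nrow(track) < 2)
    return(NA_real_)
  x <- track$centroid_x * pixel_scale
  tt <- track$time_s
  ex <- electrode_x
  s <- x - ex
  cross <- which(s[-length(s)] * s[-1] <= 0)
  if (length(cross)) {
    i <- cross[1L]
    if (x[i + 1] == x[i]) return(tt[i])
    return(tt[i] + (ex - x[i]) * (tt[i + 1] - tt[i]) / (x[i + 1] - x[i]))
  }
  # extrapolate by at most one frame-step from the nearest end
  step <- stats::median(abs(diff(x)))
  if (step == 0 || min(abs(s)) > step) return(NA_real_)
  k <- if (abs(s[1]) < abs(s[length(s)])) c(1L, 2L)
       else c(length(x) - 1L, length(x))
  slope <- (x[k[2]] - x[k[1]]) / (tt[k[2]] - tt[k[1]])
  if (slope == 0) return(NA_real_)
  tt[k[1]] + (ex - x[k[1]]) / slope
}

#' Classify a bead diameter as small or large
#'
#' @param est_diameter Estimated diameter(s) in micrometres, `> 0`.
#' @param boundary Classification boundary in micrometres; diameters
#'   strictly below it are `"small"`, all others (including exactly at the
#'   boundary) are `"large"`.
#'
#' @return Character vector of `"small"` / `"large"` labels.
#' @seealso [size_crossover()] for the default boundary between two
#'   populations.
#' @export
classify_size <- function(est_diameter, boundary) {
  if (any(!is.finite(est_diameter)) || any(est_diameter <= 0))
    pc_stop_validation("`est_diameter` must be positive and finite")
  check_scalar(boundary, "boundary", lower = 0, open_lower = TRUE)
  ifelse(est_diameter < boundary, "small", "large")
}

#' Summarise linked detections into tracks
#'
#' Computes, per track, the number of detections, the median-step velocity,
#' the interpolated electrode crossing time and the size class of the median
#' equivalent-circle diameter. Tracks with fewer than 2 detections or
#' without an electrode crossing get `NA` velocity / crossing time and are
#' excluded from matching downstream.
#'
#' @param detections Output of [link_tracks()] (with `track_id`).
#' @param vconf A [video_config()].
#' @param boundary Size-classification boundary in micrometres.
#'
#' @return Data frame with columns `track_id`, `n_detections`,
#'   `velocity_um_s`, `crossing_time_s`, `est_diameter_um`, `size_class`.
#' @export
build_tracks <- function(detections, vconf, boundary) {
  if (!is.data.frame(detections) || !"track_id" %in% names(detections))
    pc_stop_validation("`detections` must carry a `track_id` column ",
                       "(see link_tracks())")
  if (!is_video_config(vconf))
    pc_stop_validation("`vconf` must be a video_config")
  ids <- sort(unique(detections$track_id))
  rows <- lapply(ids, function(id) {
    tr <- detections[detections$track_id == id, , drop = FALSE]
    tr <- tr[order(tr$frame_index), , drop = FALSE]
    v <- if (nrow(tr) >= 2)
      estimate_velocity(tr, vconf$frame_rate, vconf$pixel_scale)
    else NA_real_
    ct <- crossing_time(tr, vconf$electrode_x, vconf$pixel_scale)
    d <- stats::median(tr$est_diameter_um)
    data.frame(track_id = id, n_detections = nrow(tr),
               velocity_um_s = abs(v), crossing_time_s = ct,
               est_diameter_um = d,
               size_class = classify_size(d, boundary))
  })
  out <- do.call(rbind, c(rows, list(empty_tracks())))
  rownames(out) <- NULL
  out
}

empty_tracks <- function() {
  data.frame(track_id = integer(0), n_detections = integer(0),
             velocity_um_s = numeric(0), crossing_time_s = numeric(0),
             est_diameter_um = numeric(0), size_class = character(0))
}
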