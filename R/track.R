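# Point tracking on the stone surface. Query points are initialized as
# a regular grid over the (eroded) segmentation mask; the reference
# tracker then follows each point frame to frame by normalized
# cross-correlation patch search (template taken from the previous
# frame, so appearance drift is tolerated at the cost of slow template
# drift — bounded in practice by the detector's re-initialization).
# A pretrained point-tracking model can replace the reference tracker
# through the external-tracks adapter in io_tables.R.

#' Initialize query points on a stone mask
#'
#' Returns the regular grid of stride `config$grid_stride` intersected
#' with the mask eroded by `config$mask_erosion` pixels, ordered
#' row-major (y outer, x inner). Deterministic.
#'
#' @param mask logical matrix (TRUE = stone pixel).
#' @param config a [tracker_config()].
#' @return A numeric matrix with columns `x`, `y` (0-based pixel
#'   coordinates); zero rows signal the no-points condition, which the
#'   caller must handle (re-segmentation or abort).
#' @export
init_points <- function(mask, config = tracker_config()) {
  if (!is.matrix(mask) || !is.logical(mask)) {
    ft_input_error("mask must be a logical matrix")
  }
  if (config$mask_erosion > 0 && any(mask)) {
    kern <- EBImage::makeBrush(2L * config$mask_erosion + 1L, shape = "disc")
    mask <- EBImage::erode(mask * 1, kern) > 0.5
  }
  H <- nrow(mask); W <- ncol(mask)
  xs <- seq(0L, W - 1L, by = config$grid_stride)
  ys <- seq(0L, H - 1L, by = config$grid_stride)
  grid <- expand.grid(x = xs, y = ys)   # x varies fastest: row-major order
  keep <- mask[cbind(grid$y + 1L, grid$x + 1L)]
  pts <- as.matrix(grid[keep, , drop = FALSE])
  rownames(pts) <- NULL
  storage.mode(pts) <- "double"
  pts
}

#' Track points through a frame sequence
#'
#' For each point and frame, the new position is the argmax of the
#' normalized cross-correlation between the point's patch (from the
#' previous frame) and all candidate patches within
#' `config$search_radius`, refined to sub-pixel accuracy by a
#' parabolic fit. A point becomes invisible when its best correlation
#' falls below `config$min_correlation` or its patch leaves the frame;
#' invisible points keep their last position and stay invisible for
#' the rest of the track segment. Objects moving faster than the
#' search radius per frame are therefore lost — the pipeline's
#' documented failure mode for small fast fragments. Tracking is
#' causal: positions at frame t depend only on frames <= t.
#'
#' @param frames a [frame_sequence()].
#' @param points K x 2 matrix of (x, y) query points.
#' @param config a [tracker_config()].
#' @param init_frame 0-based frame on which `points` were initialized.
#' @param end_frame last 0-based frame to track to (default: last
#'   frame of the sequence).
#' @return A [track_set()] spanning all frames of `frames`, visible
#'   from `init_frame` (total loss of all points is reported via
#'   visibility, never an error).
#' @export
track_points <- function(frames, points, config = tracker_config(),
                         init_frame = 0L, end_frame = NULL) {
  if (!inherits(frames, "frame_sequence")) {
    ft_input_error("track_points() needs a frame_sequence")
  }
  points <- as.matrix(points)
  if (nrow(points) < 1 || ncol(points) != 2) {
    ft_input_error("points must be a K x 2 matrix with K >= 1")
  }
  T <- frames$n_frames
  if (is.null(end_frame)) end_frame <- T - 1L
  if (init_frame < 0 || init_frame > end_frame || end_frame >= T) {
    ft_input_error("need 0 <= init_frame <= end_frame <= T-1")
  }
  K <- nrow(points)
  x <- matrix(NA_real_, K, T); y <- matrix(NA_real_, K, T)
  vis <- matrix(FALSE, K, T)
  x[, init_frame + 1L] <- points[, 1]
  y[, init_frame + 1L] <- points[, 2]
  vis[, init_frame + 1L] <- TRUE
  if (end_frame > init_frame) {
    for (t in (init_frame + 1L):end_frame) {
      st <- .ncc_step(frames$frames[[t]], frames$frames[[t + 1L]],
                      x[, t], y[, t], vis[, t],
                      config$patch_size, config$search_radius,
                      config$min_correlation)
      x[, t + 1L] <- st$x
      y[, t + 1L] <- st$y
      vis[, t + 1L] <- st$visible
    }
    if (!any(vis[, end_frame + 1L])) {
      ft_log("all %d points lost by frame %d", K, end_frame)
    }
  }
  track_set(x, y, vis, init_frame = init_frame)
}
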