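# In-memory domain types. All are lightweight S3 lists; every module
# consumes and produces only these.

#' Construct a frame sequence
#'
#' An ordered set of grayscale frames with a common size and a frame
#' rate. Intensities live in \[0, 1\]; frame indices are 0-based.
#'
#' @param frames list of numeric H x W matrices with values in \[0, 1\].
#' @param frame_rate frames per second (default 30, the native rate of
#'   single-use flexible ureteroscopes this pipeline targets).
#' @return An object of class `frame_sequence` with elements `frames`,
#'   `frame_rate`, `n_frames`.
#' @export
frame_sequence <- function(frames, frame_rate = 30) {
  if (!is.list(frames) || length(frames) == 0) {
    ft_input_error("a frame sequence needs at least one frame")
  }
  if (!is.numeric(frame_rate) || length(frame_rate) != 1 || frame_rate <= 0) {
    ft_config_error("frame_rate must be a single positive number")
  }
  dims <- vapply(frames, function(f) {
    if (!is.matrix(f) || !is.numeric(f)) {
      ft_format_error("every frame must be a numeric matrix")
    }
    dim(f)
  }, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    ft_format_error("all frames must share one height and width")
  }
  structure(
    list(frames = frames, frame_rate = as.numeric(frame_rate),
         n_frames = length(frames)),
    class = "frame_sequence"
  )
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<frame_sequence> %d frames, %dx%d px, %.6g fps (%.2f s)\n",
              x$n_frames, d[1], d[2], x$frame_rate, x$n_frames / x$frame_rate))
  invisible(x)
}

#' Construct a mask sequence
#'
#' Per-frame binary masks (TRUE = stone or fragment pixel) aligned 1:1
#' with a frame sequence.
#'
#' @param masks list of logical H x W matrices.
#' @return An object of class `mask_sequence`.
#' @export
mask_sequence <- function(masks) {
  if (!is.list(masks) || length(masks) == 0) {
    ft_input_error("a mask sequence needs at least one mask")
  }
  dims <- vapply(masks, function(m) {
    if (!is.matrix(m) || !is.logical(m)) {
      ft_format_error("every mask must be a logical matrix (strictly binary)")
    }
    if (anyNA(m)) ft_format_error("masks must not contain NA")
    dim(m)
  }, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    ft_format_error("all masks must share one height and width")
  }
  structure(list(masks = masks, n_frames = length(masks)),
            class = "mask_sequence")
}

#' @export
print.mask_sequence <- function(x, ...) {
  d <- dim(x$masks[[1]])
  cat(sprintf("<mask_sequence> %d masks, %dx%d px\n", x$n_frames, d[1], d[2]))
  invisible(x)
}

#' Construct a set of event intervals
#'
#' Ground-truth or predicted fragmentation intervals in frame
#' coordinates, inclusive on both ends, sorted by start frame.
#'
#' @param start_frame,end_frame integer vectors of equal length
#'   (0-based, inclusive).
#' @return A data.frame of class `event_intervals` with columns
#'   `start_frame`, `end_frame`, sorted by `start_frame`.
#' @export
event_intervals <- function(start_frame = integer(), end_frame = integer()) {
  if (length(start_frame) != length(end_frame)) {
    ft_format_error("start_frame and end_frame must have equal length")
  }
  if (length(start_frame)) {
    if (anyNA(start_frame) || anyNA(end_frame) ||
        any(start_frame != floor(start_frame)) ||
        any(end_frame != floor(end_frame))) {
      ft_format_error("event frames must be integers")
    }
    if (any(start_frame < 0)) {
      ft_validation_error("start_frame must be >= 0")
    }
    if (any(end_frame < start_frame)) {
      ft_validation_error("end_frame must be >= start_frame")
    }
  }
  ord <- order(start_frame, end_frame)
  out <- data.frame(start_frame = as.integer(start_frame)[ord],
                    end_frame = as.integer(end_frame)[ord])
  class(out) <- c("event_intervals", "data.frame")
  out
}

n_events <- function(events) nrow(events)

# total labeled frames across intervals (inclusive bounds)
event_frame_total <- function(events) {
  if (nrow(events) == 0) return(0L)
  sum(events$end_frame - events$start_frame + 1L)
}

#' Construct a track set
#'
#' Per-point, per-frame sub-pixel positions with visibility flags.
#' Rows index the K tracked points, columns the T frames. Positions are
#' `NA` (and visibility `FALSE`) before `init_frame`.
#'
#' @param x,y numeric K x T matrices of 0-based pixel coordinates
#'   (x = column, y = row).
#' @param visible logical K x T matrix.
#' @param init_frame 0-based frame at which the points were initialized.
#' @return An object of class `track_set`.
#' @export
track_set <- function(x, y, visible, init_frame = 0L) {
  if (!is.matrix(x) || !is.matrix(y) || !is.matrix(visible) ||
      !all(dim(x) == dim(y)) || !all(dim(x) == dim(visible))) {
    ft_format_error("x, y, visible must be K x T matrices of equal shape")
  }
  if (nrow(x) < 1) ft_validation_error("a track set needs at least one point (K >= 1)")
  if (init_frame < 0 || init_frame >= ncol(x)) {
    ft_validation_error("init_frame must lie within 0..T-1")
  }
  visible <- visible & !is.na(visible)
  if (init_frame > 0) {
    if (any(visible[, seq_len(init_frame), drop = FALSE])) {
      ft_validation_error("points cannot be visible before init_frame")
    }
  }
  if (any(!is.finite(x[visible])) || any(!is.finite(y[visible]))) {
    ft_validation_error("positions must be finite wherever visible")
  }
  structure(
    list(x = x, y = y, visible = visible,
         init_frame = as.integer(init_frame),
         n_points = nrow(x), n_frames = ncol(x)),
    class = "track_set"
  )
}

#' @export
print.track_set <- function(x, ...) {
  cat(sprintf("<track_set> %d points x %d frames, init at frame %d, %.1f%% visible\n",
              x$n_points, x$n_frames, x$init_frame, 100 * mean(x$visible)))
  invisible(x)
}

# visible (x, y) positions at 0-based frame t, as a 2-column matrix
visible_positions <- function(tracks, t) {
  j <- t + 1L
  keep <- tracks$visible[, j]
  cbind(x = tracks$x[keep, j], y = tracks$y[keep, j])
}
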