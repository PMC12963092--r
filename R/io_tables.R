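# Tabular artifacts: event intervals (CSV or JSON) and point tracks
# (CSV with columns track_id, frame, x, y, visible). All frame indices
# on disk are 0-based, matching the in-memory convention.

#' Read fragmentation event intervals
#'
#' @param path CSV with header `start_frame,end_frame`, or a JSON list
#'   of objects with those fields.
#' @return An [event_intervals()] data.frame, sorted by start frame.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) ft_input_error("event file not found: %s", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    doc <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    if (length(doc) == 0) return(event_intervals())
    if (!is.data.frame(doc)) doc <- as.data.frame(doc)
    tab <- doc
  } else {
    tab <- utils::read.csv(path)
  }
  need <- c("start_frame", "end_frame")
  if (!all(need %in% names(tab))) {
    ft_format_error("event table must have columns start_frame,end_frame")
  }
  if (nrow(tab) == 0) return(event_intervals())
  for (col in need) {
    v <- tab[[col]]
    if (!is.numeric(v) || anyNA(v) || any(v != floor(v))) {
      ft_format_error("column %s must be integer frames", col)
    }
  }
  event_intervals(tab$start_frame, tab$end_frame)
}

#' Write fragmentation event intervals
#'
#' Format follows the file extension: `.json` writes a JSON list,
#' anything else a CSV with header `start_frame,end_frame`.
#'
#' @param events an [event_intervals()] data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  df <- data.frame(start_frame = events$start_frame,
                   end_frame = events$end_frame)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(df, path, dataframe = "rows")
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a track set from CSV
#'
#' The table must hold columns `track_id, frame, x, y, visible`, with
#' every track covering the same complete 0-based frame range exactly
#' once. Positions may be empty/NA on frames where the point is not
#' visible.
#'
#' @param path CSV file.
#' @return A [track_set()].
#' @export
read_tracks <- function(path) {
  if (!file.exists(path)) ft_input_error("track file not found: %s", path)
  tab <- utils::read.csv(path)
  need <- c("track_id", "frame", "x", "y", "visible")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    ft_format_error("track table missing column(s): %s",
                    paste(miss, collapse = ", "))
  }
  if (nrow(tab) == 0) ft_format_error("track table is empty (K >= 1 required)")
  if (anyDuplicated(tab[, c("track_id", "frame")])) {
    ft_format_error("duplicated (track_id, frame) rows")
  }
  ids <- sort(unique(tab$track_id))
  frames <- sort(unique(tab$frame))
  t_max <- max(frames)
  full <- 0:t_max
  K <- length(ids); T <- length(full)
  if (!identical(as.integer(frames), as.integer(full)) ||
      nrow(tab) != K * T) {
    ft_format_error("every track must cover frames 0..%d exactly once", t_max)
  }
  o <- order(match(tab$track_id, ids), tab$frame)
  tab <- tab[o, ]
  x <- matrix(as.numeric(tab$x), nrow = K, ncol = T, byrow = TRUE)
  y <- matrix(as.numeric(tab$y), nrow = K, ncol = T, byrow = TRUE)
  vis <- matrix(as.logical(tab$visible), nrow = K, ncol = T, byrow = TRUE)
  if (anyNA(vis)) ft_format_error("visible column must be strictly 0/1")
  init <- if (any(vis)) min(which(apply(vis, 2, any))) - 1L else 0L
  track_set(x, y, visible = vis, init_frame = init)
}

#' Write a track set to CSV
#'
#' @param tracks a [track_set()].
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  K <- tracks$n_points; T <- tracks$n_frames
  df <- data.frame(
    track_id = rep(seq_len(K) - 1L, each = T),
    frame = rep(0:(T - 1L), times = K),
    x = as.vector(t(tracks$x)),
    y = as.vector(t(tracks$y)),
    visible = as.integer(as.vector(t(tracks$visible)))
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Load externally produced point tracks
#'
#' Adapter so tracks from a pretrained point-tracking model, exported
#' in the package's CSV format, can be scored by the detection and
#' evaluation stages.
#'
#' @param path CSV file as written by [write_tracks()].
#' @return A validated [track_set()].
#' @export
external_tracks <- function(path) read_tracks(path)
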