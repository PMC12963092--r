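# Decision stage: per-frame clustering of tracked point positions and
# the cluster-count rule. At every point (re)initialization the
# baseline B is *measured* as the cluster count on that frame (a stone
# may legitimately start as more than one cluster, e.g. under partial
# occlusion); a fragmentation flag fires when the count exceeds B for
# `persistence` consecutive frames, and the flag is applied to every
# frame of the qualifying run. persistence = 1 reproduces the literal
# fire-on-any-increase rule.
#
# Re-initialization is debounce-aware: a baseline measured *during* a
# rising run would swallow an event that happens to straddle the
# re-init frame, so an above-baseline run that is active when a
# re-initialization occurs keeps testing against its own baseline
# until the run resolves; the freshly measured baseline applies from
# then on.

# counts: per-frame cluster counts; seg_of: per-frame 1-based segment
# id (0 = before init); baselines: per-segment measured baseline
# (NA = detection suspended). Returns the per-frame above-baseline
# indicator and the flags after the persistence filter.
.cluster_rule_flags <- function(counts, seg_of, baselines, p) {
  T <- length(counts)
  above <- logical(T)
  b_used <- rep(NA_real_, T)
  for (t in seq_len(T)) {
    sid <- seg_of[t]
    if (sid == 0L || is.na(baselines[sid])) next
    B <- baselines[sid]
    if (t > 1L && above[t - 1L] && !is.na(b_used[t - 1L]) &&
        b_used[t - 1L] < B && counts[t] > b_used[t - 1L]) {
      B <- b_used[t - 1L]   # carry the run's baseline across the re-init
    }
    above[t] <- counts[t] > B
    b_used[t] <- B
  }
  flags <- logical(T)
  if (any(above)) {
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in seq_along(r$values)) {
      if (r$values[i] && r$lengths[i] >= p) flags[starts[i]:ends[i]] <- TRUE
    }
  }
  flags
}

.flags_to_events <- function(flags) {
  if (!any(flags)) return(event_intervals())
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  event_intervals(start_frame = starts[keep] - 1L,
                  end_frame = ends[keep] - 1L)
}

.detection_result <- function(flags, counts, reinit, baselines) {
  structure(list(pred_flags = flags,
                 pred_events = .flags_to_events(flags),
                 cluster_count = counts,
                 reinit_frames = reinit,
                 baselines = baselines),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("<detection_result> %d frames, %d predicted event(s), %d re-init(s)\n",
              length(x$pred_flags), nrow(x$pred_events), length(x$reinit_frames)))
  invisible(x)
}

#' Detect fragmentation from an existing track set
#'
#' Runs the cluster-count rule over a fixed [track_set()] (e.g. oracle
#' tracks from the simulator, or tracks imported from a pretrained
#' point tracker). Only visible points enter the clustering — frozen
#' invisible points would form phantom clusters. Re-initialization
#' events (every `reinit_interval` frames, or when the visible
#' fraction drops below `min_visible_fraction`) reset the baseline to
#' the cluster count measured on that frame; with a fixed track set no
#' actual re-sampling is possible, so re-initialization is
#' baseline-reset only (see [run_pipeline()] for true re-sampling).
#' Deterministic and causal: the flag at frame t depends only on
#' frames <= t.
#'
#' @param tracks a [track_set()].
#' @param config a [detector_config()].
#' @return A `detection_result` with per-frame flags and cluster
#'   counts, consolidated predicted events, and the re-init frames.
#' @export
detect_tracks <- function(tracks, config = detector_config()) {
  if (!inherits(tracks, "track_set")) {
    ft_input_error("detect_tracks() needs a track_set")
  }
  T <- tracks$n_frames
  counts <- integer(T)
  for (t in tracks$init_frame:(T - 1L)) {
    pos <- visible_positions(tracks, t)
    counts[t + 1L] <- if (nrow(pos)) {
      cluster_count(cluster_positions(pos, config$cluster))
    } else 0L
  }
  visfrac <- colMeans(tracks$visible)
  seg_of <- integer(T)
  reinit <- integer(0)
  baselines <- integer(0)
  t0 <- tracks$init_frame
  while (t0 <= T - 1L) {
    reinit <- c(reinit, t0)
    t_end <- min(t0 + config$reinit_interval - 1L, T - 1L)
    seg <- t0:t_end
    collapse <- seg[seg > t0 &
                      visfrac[seg + 1L] < config$min_visible_fraction]
    if (length(collapse)) {
      t_end <- collapse[1] - 1L
      seg <- t0:t_end
    }
    if (!any(tracks$visible[, t0 + 1L])) {
      baselines <- c(baselines, NA_integer_)
      ft_warn("no visible points at re-init frame %d; detection suspended", t0)
    } else {
      baselines <- c(baselines, counts[t0 + 1L])
    }
    seg_of[seg + 1L] <- length(reinit)
    t0 <- t_end + 1L
  }
  flags <- .cluster_rule_flags(counts, seg_of, baselines, config$persistence)
  .detection_result(flags, counts, reinit, baselines)
}

#' Run the full detection pipeline over a frame sequence
#'
#' Orchestrates segment -> track -> detect with true point
#' re-sampling: at frame 0, every `reinit_interval` frames, and
#' whenever the visible fraction of the current point set drops below
#' `min_visible_fraction`, points are re-initialized from the current
#' stone mask and the cluster-count baseline is re-measured. If a
#' re-initialization finds no points, detection is suspended (flags
#' stay FALSE) until a later re-initialization succeeds, with a logged
#' warning.
#'
#' @param frames a [frame_sequence()].
#' @param masks optional [mask_sequence()] of precomputed masks (e.g.
#'   from a neural segmenter, or simulator ground truth); when `NULL`
#'   the reference segmenter runs with `segment_cfg`.
#' @param detect_cfg a [detector_config()].
#' @param track_cfg a [tracker_config()].
#' @param segment_cfg a [segment_config()].
#' @return A `detection_result`; the mask sequence used is attached as
#'   attribute `"masks"`.
#' @export
run_pipeline <- function(frames, masks = NULL,
                         detect_cfg = detector_config(),
                         track_cfg = tracker_config(),
                         segment_cfg = segment_config()) {
  if (!inherits(frames, "frame_sequence")) {
    ft_input_error("run_pipeline() needs a frame_sequence")
  }
  T <- frames$n_frames
  if (is.null(masks)) {
    masks <- segment_sequence(frames, config = segment_cfg)
  }
  if (!inherits(masks, "mask_sequence") || masks$n_frames != T) {
    ft_input_error("masks must be a mask_sequence aligned with the frames")
  }
  counts <- integer(T)
  seg_of <- integer(T)
  reinit <- integer(0)
  baselines <- integer(0)
  t0 <- 0L
  while (t0 <= T - 1L) {
    reinit <- c(reinit, t0)
    t_sched <- min(t0 + detect_cfg$reinit_interval - 1L, T - 1L)
    pts <- init_points(masks$masks[[t0 + 1L]], track_cfg)
    if (nrow(pts) == 0) {
      baselines <- c(baselines, NA_integer_)
      seg_of[(t0:t_sched) + 1L] <- length(reinit)
      ft_warn("no points on the mask at re-init frame %d; detection suspended", t0)
      t0 <- t_sched + 1L
      next
    }
    tracks <- track_points(frames, pts, track_cfg,
                           init_frame = t0, end_frame = t_sched)
    seg <- t0:t_sched
    for (t in seg) {
      pos <- visible_positions(tracks, t)
      counts[t + 1L] <- if (nrow(pos)) {
        cluster_count(cluster_positions(pos, detect_cfg$cluster))
      } else 0L
    }
    visfrac <- colMeans(tracks$visible[, seg + 1L, drop = FALSE])
    collapse <- seg[seq_along(seg) > 1 &
                      visfrac < detect_cfg$min_visible_fraction]
    t_end <- if (length(collapse)) collapse[1] - 1L else t_sched
    baselines <- c(baselines, counts[t0 + 1L])
    seg_of[(t0:t_end) + 1L] <- length(reinit)
    t0 <- t_end + 1L
  }
  flags <- .cluster_rule_flags(counts, seg_of, baselines,
                               detect_cfg$persistence)
  res <- .detection_result(flags, counts, reinit, baselines)
  attr(res, "masks") <- masks
  res
}
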