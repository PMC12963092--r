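# Evaluation protocol: frame-level and segment-level TP/FP/FN with a
# tolerance window, and precision/recall/F1 from pooled counts.
#
# Frame level: a ground-truth interval [s, e] is matched when any
# predicted frame q satisfies s - tol <= q <= e + tol; a matched
# interval credits all of its frames as TP exactly once, an unmatched
# interval counts all of its frames as FN, and every predicted frame
# matching no interval is one FP (per-frame FP is the only unit
# consistent with the per-frame TP/FN accounting).
#
# Segment level: the video is tiled into consecutive segments of
# `segment_len` frames. TP counts matched ground-truth events (so
# TP + FN always equals the number of labeled events); FP counts
# segments holding at least one predicted frame yet intersecting no
# tolerance-widened event.

.eval_counts <- function(level, tp, fp, fn) {
  if (tp < 0 || fp < 0 || fn < 0) ft_validation_error("counts must be >= 0")
  structure(list(level = level, tp = as.numeric(tp), fp = as.numeric(fp),
                 fn = as.numeric(fn)),
            class = "eval_counts")
}

#' Construct an evaluation count triple
#'
#' @param level `"frame"` or `"segment"`.
#' @param tp,fp,fn non-negative counts.
#' @return An object of class `eval_counts`.
#' @export
eval_counts <- function(level = c("frame", "segment"), tp = 0, fp = 0, fn = 0) {
  level <- match.arg(level)
  .eval_counts(level, tp, fp, fn)
}

#' @export
print.eval_counts <- function(x, ...) {
  cat(sprintf("<eval_counts> %s-level: TP=%g FP=%g FN=%g\n",
              x$level, x$tp, x$fp, x$fn))
  invisible(x)
}

.check_events <- function(gt_events) {
  if (!inherits(gt_events, "event_intervals")) {
    gt_events <- event_intervals(gt_events$start_frame, gt_events$end_frame)
  }
  if (nrow(gt_events) > 1) {
    s <- gt_events$start_frame; e <- gt_events$end_frame
    if (any(s[-1] <= e[-nrow(gt_events)])) {
      ft_validation_error("ground-truth events must not overlap")
    }
  }
  gt_events
}

.normalize_pred <- function(pred_frames) {
  pred_frames <- as.integer(pred_frames)
  if (length(pred_frames) && (is.unsorted(pred_frames) ||
                              anyDuplicated(pred_frames))) {
    ft_warn("predicted frames normalized (sorted, duplicates dropped)")
    pred_frames <- sort(unique(pred_frames))
  }
  pred_frames
}

#' Frame-level matching of predictions against labeled events
#'
#' @param pred_frames sorted 0-based predicted frame numbers (every
#'   frame flagged as fragmentation); unsorted or duplicated input is
#'   normalized with a warning.
#' @param gt_events an [event_intervals()] data.frame of non-overlapping
#'   ground-truth events.
#' @param config an [eval_config()].
#' @return A list with `counts` (frame-level [eval_counts()]),
#'   `matched_events` (logical per ground-truth event) and
#'   `matched_preds` (logical per predicted frame).
#' @export
match_frame_level <- function(pred_frames, gt_events,
                              config = eval_config()) {
  gt_events <- .check_events(gt_events)
  pred_frames <- .normalize_pred(pred_frames)
  tol <- config$tolerance_frames
  nE <- nrow(gt_events)
  matched_events <- logical(nE)
  matched_preds <- logical(length(pred_frames))
  if (nE && length(pred_frames)) {
    for (i in seq_len(nE)) {
      lo <- gt_events$start_frame[i] - tol
      hi <- gt_events$end_frame[i] + tol
      hit <- pred_frames >= lo & pred_frames <= hi
      matched_events[i] <- any(hit)
      matched_preds <- matched_preds | hit
    }
  }
  len <- if (nE) gt_events$end_frame - gt_events$start_frame + 1L else integer(0)
  counts <- .eval_counts("frame",
                         tp = sum(len[matched_events]),
                         fp = sum(!matched_preds),
                         fn = sum(len[!matched_events]))
  list(counts = counts, matched_events = matched_events,
       matched_preds = matched_preds)
}

#' Segment-level accounting
#'
#' @param pred_frames sorted 0-based predicted frames.
#' @param matched_events logical per ground-truth event, from
#'   [match_frame_level()].
#' @param gt_events the same [event_intervals()] passed to
#'   [match_frame_level()].
#' @param total_frames video length T (frames are tiled into
#'   consecutive segments of `config$segment_len`; the last segment
#'   may be short).
#' @param config an [eval_config()]. With the default
#'   `segment_tp_unit = "event"`, TP counts matched ground-truth
#'   events, which makes TP + FN equal the number of labeled events;
#'   `"segment"` counts one TP per segment containing a matched
#'   prediction instead.
#' @return A segment-level [eval_counts()].
#' @export
match_segment_level <- function(pred_frames, matched_events, gt_events,
                                total_frames, config = eval_config()) {
  gt_events <- .check_events(gt_events)
  pred_frames <- .normalize_pred(pred_frames)
  tol <- config$tolerance_frames
  if (length(pred_frames) && max(pred_frames) >= total_frames) {
    ft_validation_error("predicted frame beyond total_frames")
  }
  if (nrow(gt_events) && max(gt_events$end_frame) >= total_frames) {
    ft_validation_error("ground-truth event beyond total_frames")
  }
  if (length(matched_events) != nrow(gt_events)) {
    ft_validation_error("matched_events must align with gt_events")
  }
  L <- config$segment_len
  # segments holding >= 1 predicted frame but intersecting no
  # tolerance-widened event are false positives
  fp <- 0L
  if (length(pred_frames)) {
    segs <- unique(pred_frames %/% L)
    for (sg in segs) {
      a <- sg * L
      b <- min((sg + 1L) * L - 1L, total_frames - 1L)
      touches <- nrow(gt_events) > 0 &&
        any(gt_events$start_frame - tol <= b & gt_events$end_frame + tol >= a)
      if (!touches) fp <- fp + 1L
    }
  }
  if (config$segment_tp_unit == "event") {
    tp <- sum(matched_events)
    fn <- sum(!matched_events)
  } else {
    # literal reading: one TP per segment containing a matched prediction
    mp <- pred_frames[.match_pred_flags(pred_frames, gt_events, tol)]
    tp <- length(unique(mp %/% L))
    fn <- sum(!matched_events)
  }
  counts <- .eval_counts("segment", tp = tp, fp = fp, fn = fn)
  # conservation invariant under the default unit: every labeled event
  # is either detected or missed
  if (config$segment_tp_unit == "event") {
    stopifnot(counts$tp + counts$fn == nrow(gt_events))
  }
  counts
}

.match_pred_flags <- function(pred_frames, gt_events, tol) {
  out <- logical(length(pred_frames))
  for (i in seq_len(nrow(gt_events))) {
    out <- out | (pred_frames >= gt_events$start_frame[i] - tol &
                    pred_frames <= gt_events$end_frame[i] + tol)
  }
  out
}

#' Precision, recall and F1 from a count triple
#'
#' Precision = TP/(TP+FP), recall = TP/(TP+FN), F1 their harmonic
#' mean; each is 0 by convention when its denominator is 0.
#'
#' @param counts an [eval_counts()].
#' @return A list of class `metrics` with `precision`, `recall`, `f1`.
#' @export
compute_metrics <- function(counts) {
  if (!inherits(counts, "eval_counts")) {
    ft_input_error("compute_metrics() needs eval_counts")
  }
  precision <- if (counts$tp + counts$fp > 0) counts$tp / (counts$tp + counts$fp) else 0
  recall <- if (counts$tp + counts$fn > 0) counts$tp / (counts$tp + counts$fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  structure(list(precision = precision, recall = recall, f1 = f1),
            class = "metrics")
}

#' @export
print.metrics <- function(x, ...) {
  cat(sprintf("<metrics> precision %.3f, recall %.3f, F1 %.3f\n",
              x$precision, x$recall, x$f1))
  invisible(x)
}

#' Pool evaluation counts across cases
#'
#' Counts are summed element-wise; metrics are then recomputed from
#' the pooled counts, never averaged across cases.
#'
#' @param per_case_counts non-empty list of [eval_counts()] at the
#'   same level.
#' @return A pooled [eval_counts()].
#' @export
aggregate_counts <- function(per_case_counts) {
  if (!is.list(per_case_counts) || length(per_case_counts) == 0 ||
      !all(vapply(per_case_counts, inherits, logical(1), "eval_counts"))) {
    ft_validation_error("need a non-empty list of eval_counts")
  }
  levels <- vapply(per_case_counts, `[[`, character(1), "level")
  if (length(unique(levels)) != 1) {
    ft_validation_error("cannot pool counts from different levels")
  }
  .eval_counts(levels[1],
               tp = sum(vapply(per_case_counts, `[[`, numeric(1), "tp")),
               fp = sum(vapply(per_case_counts, `[[`, numeric(1), "fp")),
               fn = sum(vapply(per_case_counts, `[[`, numeric(1), "fn")))
}

#' Evaluate predictions at both levels
#'
#' Convenience wrapper running [match_frame_level()] and
#' [match_segment_level()] and deriving metrics from each.
#'
#' @param pred predicted frames (integer vector) or a per-frame
#'   logical flag vector of length `total_frames`.
#' @param gt_events ground-truth [event_intervals()].
#' @param total_frames video length T.
#' @param config an [eval_config()].
#' @return List with `frame` and `segment`, each holding `counts` and
#'   `metrics`, plus the frame-level match flags.
#' @export
evaluate_events <- function(pred, gt_events, total_frames,
                            config = eval_config()) {
  pred_frames <- if (is.logical(pred)) {
    if (length(pred) != total_frames) {
      ft_validation_error("flag vector must have length total_frames")
    }
    which(pred) - 1L
  } else {
    as.integer(pred)
  }
  fr <- match_frame_level(pred_frames, gt_events, config)
  sg <- match_segment_level(sort(unique(pred_frames)), fr$matched_events,
                            gt_events, total_frames, config)
  list(frame = list(counts = fr$counts, metrics = compute_metrics(fr$counts)),
       segment = list(counts = sg, metrics = compute_metrics(sg)),
       matched_events = fr$matched_events,
       matched_preds = fr$matched_preds)
}
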