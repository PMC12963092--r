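# Evaluation protocol: tolerance-window matching and pooled metrics.

test_that("frame-level matching credits intervals once", {
  gt <- event_intervals(100L, 110L)
  cfg <- eval_config()

  # a single early prediction within the 30-frame tolerance matches
  r <- match_frame_level(85L, gt, cfg)
  expect_equal(r$counts$tp, 11)
  expect_equal(r$counts$fp, 0)
  expect_equal(r$counts$fn, 0)

  # no predictions: the whole interval is false negatives
  r <- match_frame_level(integer(0), gt, cfg)
  expect_equal(r$counts$tp, 0)
  expect_equal(r$counts$fn, 11)
  expect_equal(r$counts$fp, 0)

  # multiple matching predictions still credit the interval once;
  # a prediction beyond end+tolerance is one false positive
  r <- match_frame_level(c(85L, 105L, 300L), gt, cfg)
  expect_equal(r$counts$tp, 11)
  expect_equal(r$counts$fp, 1)
  expect_equal(r$counts$fn, 0)
  expect_equal(r$matched_preds, c(TRUE, TRUE, FALSE))
})

test_that("segment-level accounting conserves events and flags empty segments", {
  cfg <- eval_config()
  # one stray prediction, no labeled events, T = 300: only segment 0 fires
  fr <- match_frame_level(10L, event_intervals(), cfg)
  sg <- match_segment_level(10L, fr$matched_events, event_intervals(),
                            300L, cfg)
  expect_equal(sg$fp, 1)
  expect_equal(sg$tp, 0)
  expect_equal(sg$fn, 0)

  # no predictions at all: no false positives regardless of ground truth
  gt <- event_intervals(c(10L, 200L), c(20L, 230L))
  fr <- match_frame_level(integer(0), gt, cfg)
  sg <- match_segment_level(integer(0), fr$matched_events, gt, 300L, cfg)
  expect_equal(sg$fp, 0)
  expect_equal(sg$tp, 0)
  expect_equal(sg$fn, 2)

  # TP + FN equals the number of labeled events
  fr <- match_frame_level(c(15L, 90L), gt, cfg)
  sg <- match_segment_level(c(15L, 90L), fr$matched_events, gt, 300L, cfg)
  expect_equal(sg$tp + sg$fn, nrow(gt))
})

test_that("metrics follow the harmonic-mean definition with 0 conventions", {
  m <- compute_metrics(eval_counts("frame", tp = 2, fp = 1, fn = 2))
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$recall, 1 / 2)
  expect_equal(m$f1, 2 * (2 / 3) * (1 / 2) / (2 / 3 + 1 / 2))
  z <- compute_metrics(eval_counts("frame", 0, 0, 0))
  expect_equal(c(z$precision, z$recall, z$f1), c(0, 0, 0))
})

test_that("aggregation pools counts before recomputing metrics", {
  a <- eval_counts("segment", tp = 1, fp = 0, fn = 1)
  b <- eval_counts("segment", tp = 3, fp = 2, fn = 1)
  pooled <- aggregate_counts(list(a, b))
  expect_equal(c(pooled$tp, pooled$fp, pooled$fn), c(4, 2, 2))
  expect_equal(compute_metrics(pooled)$precision, 4 / 6, tolerance = 1e-12)
  expect_equal(aggregate_counts(list(a)), a)
  expect_error(aggregate_counts(list()), class = "fragtrack_validation_error")
  expect_error(aggregate_counts(list(a, eval_counts("frame", 1, 1, 1))),
               class = "fragtrack_validation_error")
})

test_that("matching equals the brute-force all-pairs oracle on random instances", {
  set.seed(303)
  cfg <- eval_config()
  for (i in 1:60) {
    inst <- random_eval_instance()
    fr <- match_frame_level(inst$pred, inst$events, cfg)
    or <- oracle_match_frame(inst$pred, inst$events, cfg$tolerance_frames)
    expect_equal(fr$counts$tp, or$tp)
    expect_equal(fr$counts$fp, or$fp)
    expect_equal(fr$counts$fn, or$fn)
    sg <- match_segment_level(inst$pred, fr$matched_events, inst$events,
                              inst$total, cfg)
    os <- oracle_match_segment(inst$pred, or$ev_matched, inst$events,
                               inst$total, cfg$tolerance_frames,
                               cfg$segment_len)
    expect_equal(sg$tp, os$tp)
    expect_equal(sg$fp, os$fp)
    expect_equal(sg$fn, os$fn)
  }
})

test_that("widening the tolerance never hurts true positives", {
  set.seed(404)
  for (i in 1:20) {
    inst <- random_eval_instance()
    prev_tp <- -1; prev_fn <- Inf
    for (tol in c(0, 10, 30, 60)) {
      fr <- match_frame_level(inst$pred, inst$events,
                              eval_config(tolerance_frames = tol))
      expect_gte(fr$counts$tp, prev_tp)
      expect_lte(fr$counts$fn, prev_fn)
      prev_tp <- fr$counts$tp; prev_fn <- fr$counts$fn
    }
  }
})

test_that("input hygiene: overlaps rejected, unsorted predictions normalized", {
  overlapping <- data.frame(start_frame = c(10L, 15L), end_frame = c(20L, 30L))
  expect_error(match_frame_level(5L, overlapping),
               class = "fragtrack_validation_error")
  gt <- event_intervals(100L, 110L)
  expect_warning(r <- match_frame_level(c(105L, 85L, 85L), gt), "normalized")
  expect_equal(r$counts$tp, 11)
  # prediction past the video end is a validation error at segment level
  fr <- suppressWarnings(match_frame_level(500L, gt))
  expect_error(match_segment_level(500L, fr$matched_events, gt, 300L),
               class = "fragtrack_validation_error")
})

test_that("evaluate_events ties both levels together from flag vectors", {
  T <- 300L
  gt <- event_intervals(c(190L, 250L), c(200L, 260L))
  flags <- rep(FALSE, T)
  flags[191:196] <- TRUE          # frames 190..195 hit the first event
  flags[10] <- TRUE               # frame 9: stray, segment 0 false positive
  ev <- evaluate_events(flags, gt, T)
  expect_equal(ev$frame$counts$tp, 11)
  expect_equal(ev$frame$counts$fn, 11)
  expect_equal(ev$frame$counts$fp, 1)
  expect_equal(ev$segment$counts$tp, 1)
  expect_equal(ev$segment$counts$fn, 1)
  expect_equal(ev$segment$counts$fp, 1)
  # frame-level TP+FN equals the total labeled frames
  expect_equal(ev$frame$counts$tp + ev$frame$counts$fn, 22)
})
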