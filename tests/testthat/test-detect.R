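# Density-based clustering and the cluster-count detection rule.

test_that("well-separated blobs and tight blobs cluster as expected", {
  set.seed(101)
  b1 <- cbind(rnorm(10, 0, 2), rnorm(10, 0, 2))
  b2 <- cbind(rnorm(10, 100, 2), rnorm(10, 0, 2))
  pts <- rbind(b1, b2)
  lab <- cluster_positions(pts, cluster_config(min_cluster_size = 5))
  expect_equal(cluster_count(lab), 2)
  expect_equal(sum(lab == -1), 0)
  # the independent density-connectivity oracle agrees the blobs are
  # density-separated
  expect_equal(oracle_cluster_count(pts, 5, 5), 2)
  # both blobs pure
  expect_equal(length(unique(lab[1:10])), 1)
  expect_equal(length(unique(lab[11:20])), 1)
  expect_false(lab[1] == lab[11])

  one <- cbind(rnorm(20, 50, 2), rnorm(20, 50, 2))
  expect_equal(cluster_count(cluster_positions(one)), 1)

  scattered <- cbind(c(0, 50, 100), c(0, 80, 10))
  lab3 <- cluster_positions(scattered, cluster_config(min_cluster_size = 5))
  expect_equal(lab3, rep(-1L, 3))
  expect_equal(cluster_count(lab3), 0)
})

test_that("cluster_count counts distinct non-noise labels", {
  expect_equal(cluster_count(c(0L, 0L, 1L, 1L, -1L)), 2)
  expect_equal(cluster_count(rep(-1L, 5)), 0)
  expect_equal(cluster_count(integer(0)), 0)
})

test_that("clustering is deterministic and position-only", {
  set.seed(55)
  pts <- cbind(runif(40, 0, 100), runif(40, 0, 100))
  a <- cluster_positions(pts)
  b <- cluster_positions(pts)
  expect_identical(a, b)
})

test_that("cluster counts match the exhaustive density-connectivity oracle", {
  set.seed(202)
  n_sets <- 200
  agree <- 0
  disagreements <- character(0)
  for (i in seq_len(n_sets)) {
    n <- sample(5:12, 1)
    nb <- sample(1:3, 1)
    centers <- matrix(runif(2 * nb, 0, 100), nb)
    xy <- centers[sample(nb, n, replace = TRUE), , drop = FALSE] +
      matrix(rnorm(2 * n, 0, 3), n)
    cc <- cluster_config(min_cluster_size = 3, min_samples = 3)
    a <- cluster_count(cluster_positions(xy, cc))
    b <- oracle_cluster_count(xy, 3, 3)
    if (a == b) agree <- agree + 1
    else disagreements <- c(disagreements, sprintf("set %d: %d vs %d", i, a, b))
  }
  if (length(disagreements)) {
    message("cluster-count disagreements (boundary ties): ",
            paste(disagreements, collapse = "; "))
  }
  expect_gte(agree / n_sets, 0.95)
})

test_that("the persistence rule fires only on sustained increases", {
  # counts 1,1,2,1,2,2,2 with baseline 1 and p=3: only the final run
  counts <- c(1L, 1L, 2L, 1L, 2L, 2L, 2L)
  flags <- fragtrack:::.cluster_rule_flags(counts, rep(1L, 7), 1L, 3L)
  expect_equal(which(flags) - 1L, c(4L, 5L, 6L))
  ev <- fragtrack:::.flags_to_events(flags)
  expect_equal(ev$start_frame, 4L)
  expect_equal(ev$end_frame, 6L)
  # p = 1 reproduces the literal fire-on-any-increase rule
  flags1 <- fragtrack:::.cluster_rule_flags(counts, rep(1L, 7), 1L, 1L)
  expect_equal(which(flags1) - 1L, c(2L, 4L, 5L, 6L))
})

test_that("increasing persistence never adds predicted frames", {
  set.seed(77)
  for (i in 1:20) {
    counts <- sample(1:3, 40, replace = TRUE)
    seg <- rep(1L, 40)
    prev <- NULL
    for (p in 1:5) {
      fl <- fragtrack:::.cluster_rule_flags(counts, seg, 1L, p)
      if (!is.null(prev)) expect_true(all(!fl | prev))
      prev <- fl
    }
  }
})

test_that("oracle tracks from a split scene yield one prompt event", {
  cfg <- scene_config(n_frames = 100, n_track_points = 200,
                      events = list(fragment_spec(split_frame = 50,
                                                  area_fraction = 0.25,
                                                  velocity = c(6, 0),
                                                  lifetime = 40)),
                      seed = 11)
  sc <- generate_scene(cfg)
  res <- detect_tracks(sc$gt_tracks, detector_config(persistence = 3))
  expect_equal(nrow(res$pred_events), 1)
  # the density gap needs a few frames to open; p = 3 adds no delay to
  # the run start because the whole qualifying run is flagged
  expect_gte(res$pred_events$start_frame[1], 50)
  expect_lte(res$pred_events$start_frame[1], 55)
})

test_that("a static scene produces no flags", {
  cfg <- quiet_scene(n_frames = 40, seed = 19, jitter_sd = 0.3,
                     noise_sd = 0.02)
  sc <- generate_scene(cfg)
  res <- run_pipeline(sc$frames)
  expect_false(any(res$pred_flags))
  expect_equal(nrow(res$pred_events), 0)
})

test_that("detection is suspended while no points can be initialized", {
  # blank frames: the segmenter finds nothing anywhere
  frames <- frame_sequence(replicate(6, matrix(0, 64, 64), simplify = FALSE))
  expect_warning(
    res <- run_pipeline(frames,
                        detect_cfg = detector_config(reinit_interval = 6)),
    "suspended")
  expect_false(any(res$pred_flags))
  expect_true(all(is.na(res$baselines)))

  frames12 <- frame_sequence(replicate(12, matrix(0, 64, 64), simplify = FALSE))
  res12 <- suppressWarnings(
    run_pipeline(frames12, detect_cfg = detector_config(reinit_interval = 6)))
  expect_equal(res12$reinit_frames, c(0L, 6L))
  expect_true(all(is.na(res12$baselines)))
})

test_that("detection is causal and deterministic given tracks and config", {
  cfg <- scene_config(n_frames = 80, n_track_points = 100,
                      events = list(fragment_spec(40, velocity = c(4, 0))),
                      seed = 23)
  sc <- generate_scene(cfg)
  a <- detect_tracks(sc$gt_tracks)
  b <- detect_tracks(sc$gt_tracks)
  expect_identical(a$pred_flags, b$pred_flags)
  # truncating the future does not change the past: rebuild a track
  # set cut at frame 59 and compare prefixes
  cut <- 60L
  tr <- sc$gt_tracks
  trunc <- track_set(tr$x[, 1:cut], tr$y[, 1:cut], tr$visible[, 1:cut],
                     init_frame = tr$init_frame)
  res_t <- detect_tracks(trunc)
  expect_identical(res_t$cluster_count, a$cluster_count[1:cut])
  expect_identical(res_t$pred_flags[1:(cut - 10)], a$pred_flags[1:(cut - 10)])
})
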