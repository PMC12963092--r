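# Frame, mask, event and track I/O: round trips, ordering, validation.

test_that("frame directories read back in order with luma conversion", {
  dir <- withr::local_tempdir()
  # 5 gray frames with distinct intensities, written out of creation order
  for (i in 5:1) {
    png::writePNG(matrix(i / 10, 16, 16),
                  file.path(dir, sprintf("frame_%03d.png", i - 1)))
  }
  fs <- read_frames(dir, frame_rate = 30)
  expect_s3_class(fs, "frame_sequence")
  expect_equal(fs$n_frames, 5)
  expect_equal(fs$frame_rate, 30)
  # lexicographic order == frame order; 8-bit quantization tolerance
  for (i in 1:5) {
    expect_lt(abs(fs$frames[[i]][1, 1] - i / 10), 1 / 255)
  }

  # color input collapses by Rec.601 luma weighting
  rgb <- array(0, c(8, 8, 3)); rgb[, , 1] <- 1   # pure red
  png::writePNG(rgb, file.path(dir2 <- withr::local_tempdir(), "f0.png"))
  g <- read_frames(dir2)$frames[[1]]
  expect_equal(g[1, 1], 0.299, tolerance = 2 / 255)
})

test_that("frame reading rejects empty and inconsistent input", {
  empty <- withr::local_tempdir()
  expect_error(read_frames(empty), class = "fragtrack_input_error")
  expect_error(read_frames(file.path(empty, "nope")),
               class = "fragtrack_input_error")

  dir <- withr::local_tempdir()
  png::writePNG(matrix(0.5, 64, 64), file.path(dir, "a.png"))
  png::writePNG(matrix(0.5, 32, 32), file.path(dir, "b.png"))
  expect_error(read_frames(dir), class = "fragtrack_format_error")

  single <- withr::local_tempdir()
  png::writePNG(matrix(0.2, 16, 16), file.path(single, "only.png"))
  expect_equal(read_frames(single)$n_frames, 1)
})

test_that("frames and masks round trip through PNG", {
  set.seed(11)
  frames <- frame_sequence(lapply(1:4, function(i) matrix(runif(32 * 32), 32)))
  dir <- withr::local_tempdir()
  write_frames(frames, dir)
  back <- read_frames(dir)
  expect_equal(back$n_frames, 4)
  for (i in 1:4) {
    expect_lt(max(abs(back$frames[[i]] - frames$frames[[i]])), 1 / 255)
  }
  # frame 0 written equals frame 0 read back (0-based indexing contract)
  expect_lt(max(abs(back$frames[[1]] - frames$frames[[1]])), 1 / 255)

  masks <- mask_sequence(lapply(1:4, function(i) matrix(runif(32 * 32) > 0.5, 32)))
  mdir <- withr::local_tempdir()
  write_masks(masks, mdir)
  mback <- read_masks(mdir)
  # binary masks round trip exactly, every pixel
  for (i in 1:4) expect_identical(mback$masks[[i]], masks$masks[[i]])
})

test_that("event tables round trip, sort, and validate", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("start_frame,end_frame", "100,110", "40,45"), path)
  ev <- read_events(path)
  expect_equal(ev$start_frame, c(40L, 100L))
  expect_equal(ev$end_frame, c(45L, 110L))

  # empty file with header -> empty set
  writeLines("start_frame,end_frame", path)
  expect_equal(nrow(read_events(path)), 0)

  # end < start -> validation error
  writeLines(c("start_frame,end_frame", "10,5"), path)
  expect_error(read_events(path), class = "fragtrack_validation_error")

  # non-integer -> format error
  writeLines(c("start_frame,end_frame", "1.5,7"), path)
  expect_error(read_events(path), class = "fragtrack_format_error")

  # CSV and JSON round trips
  ev <- event_intervals(c(3L, 50L, 9L), c(7L, 61L, 12L))
  for (ext in c(".csv", ".json")) {
    p <- withr::local_tempfile(fileext = ext)
    write_events(ev, p)
    expect_equal(read_events(p), ev)
  }
})

test_that("track tables round trip and reject malformed input", {
  set.seed(5)
  K <- 4; T <- 6
  x <- matrix(runif(K * T, 0, 60), K, T)
  y <- matrix(runif(K * T, 0, 60), K, T)
  vis <- matrix(TRUE, K, T)
  vis[2, 4:6] <- FALSE
  tr <- track_set(x, y, vis)
  p <- withr::local_tempfile(fileext = ".csv")
  write_tracks(tr, p)
  back <- read_tracks(p)
  expect_equal(back$x, tr$x)
  expect_equal(back$y, tr$y)
  expect_equal(back$visible, tr$visible)
  expect_equal(back$init_frame, 0L)
  expect_equal(external_tracks(p)$x, tr$x)

  tab <- utils::read.csv(p)
  # a missing frame for one track is a format error
  p2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tab[-3, ], p2, row.names = FALSE)
  expect_error(read_tracks(p2), class = "fragtrack_format_error")

  # duplicated (track_id, frame)
  utils::write.csv(rbind(tab, tab[1, ]), p2, row.names = FALSE)
  expect_error(read_tracks(p2), class = "fragtrack_format_error")

  # missing visibility column
  utils::write.csv(tab[, c("track_id", "frame", "x", "y")], p2, row.names = FALSE)
  expect_error(read_tracks(p2), class = "fragtrack_format_error")

  # empty table violates K >= 1
  utils::write.csv(tab[0, ], p2, row.names = FALSE)
  expect_error(read_tracks(p2), class = "fragtrack_format_error")
})

test_that("config loading applies defaults and rejects unknown keys", {
  p <- withr::local_tempfile(fileext = ".yaml")
  writeLines("", p)
  cfg <- load_config(p)
  expect_s3_class(cfg, "run_config")
  expect_equal(cfg$seed, 1L)
  expect_equal(cfg$detect$cluster$min_cluster_size, 5L)
  expect_equal(cfg$eval$tolerance_frames, 30L)

  writeLines(c("seed: 7", "detect:", "  persistence: 2"), p)
  cfg <- load_config(p)
  expect_equal(cfg$seed, 7L)
  expect_equal(cfg$synth$seed, 7L)
  expect_equal(cfg$detect$persistence, 2L)

  writeLines(c("detect:", "  min_cluster_size: -1"), p)
  expect_error(load_config(p), class = "fragtrack_config_error")

  writeLines("no_such_block: 1", p)
  expect_error(load_config(p), class = "fragtrack_config_error")

  writeLines(c("track:", "  warp_speed: 9"), p)
  expect_error(load_config(p), class = "fragtrack_config_error")
})

test_that("domain type invariants are enforced", {
  expect_error(frame_sequence(list()), class = "fragtrack_input_error")
  expect_error(frame_sequence(list(matrix(0, 4, 4)), frame_rate = 0),
               class = "fragtrack_config_error")
  expect_error(mask_sequence(list(matrix(0, 4, 4))),
               class = "fragtrack_format_error")
  expect_error(event_intervals(5, 3), class = "fragtrack_validation_error")
  expect_error(event_intervals(-1, 3), class = "fragtrack_validation_error")
  expect_error(track_set(matrix(1, 0, 3), matrix(1, 0, 3),
                         matrix(TRUE, 0, 3)),
               class = "fragtrack_validation_error")
})
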