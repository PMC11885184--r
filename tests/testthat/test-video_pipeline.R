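write_frames <- function(dir, frames) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(frames)) {
    write_image(frames[[i]], file.path(dir, sprintf("frame%05d.png", i - 1L)))
  }
  dir
}

test_that("frame iteration respects name order and stride", {
  spec <- scene_spec(seed = 2, n_cells = 3, height = 48, width = 48,
                     nucleus_sigma_range = c(2, 3))
  sq <- generate_sequence(spec, n_frames = 10, drift_px_per_frame = c(1, 0))
  dir <- write_frames(tempfile("frames"), sq$frames)

  src <- frame_source(dir, stride = 1)
  frames <- iterate_frames(src)
  expect_length(frames, 10)
  expect_equal(vapply(frames, `[[`, integer(1), "frame_index"), 0:9)

  src5 <- frame_source(dir, stride = 5)
  frames5 <- iterate_frames(src5)
  expect_length(frames5, 2)
  expect_equal(vapply(frames5, `[[`, integer(1), "frame_index"), c(0L, 5L))

  empty <- tempfile("empty"); dir.create(empty)
  expect_warning(src0 <- frame_source(empty), "no frame images")
  expect_length(iterate_frames(src0), 0)
})

test_that("process_sequence writes per-frame artifacts and a config snapshot", {
  spec <- scene_spec(seed = 15, n_cells = 6, height = 96, width = 96)
  sq <- generate_sequence(spec, n_frames = 3, drift_px_per_frame = c(2, 0))
  dir <- write_frames(tempfile("frames"), sq$frames)
  out <- tempfile("run")
  cfg <- run_config(output_dir = out, log_level = "quiet")

  res <- process_sequence(frame_source(dir), cfg)
  expect_equal(nrow(res$counts), 3)
  expect_true(file.exists(file.path(out, "blobs.csv")))
  expect_true(file.exists(file.path(out, "counts.csv")))
  expect_true(file.exists(file.path(out, "run_config.yaml")))
  expect_true(file.exists(file.path(out, "segments.csv")))
  expect_gt(length(list.files(out, pattern = "^frame\\d+_blob\\d+\\.png$")), 0)

  blobs <- read_blobs(file.path(out, "blobs.csv"))
  expect_setequal(unique(blobs$frame), 0:2)
  expect_equal(res$summary$n_frames, 3)
  expect_equal(res$summary$total_blobs, sum(res$counts$n_cells))
})

test_that("a static scene yields identical blob lists on every frame", {
  spec <- scene_spec(seed = 23, n_cells = 5, height = 96, width = 96)
  sq <- generate_sequence(spec, n_frames = 4, drift_px_per_frame = c(0, 0))
  dir <- write_frames(tempfile("frames"), sq$frames)
  out <- tempfile("run")
  res <- process_sequence(frame_source(dir),
                          run_config(output_dir = out, log_level = "quiet"),
                          write_segments = FALSE)
  per_frame <- split(res$blobs[c("x", "y", "sigma", "response")],
                     res$blobs$frame)
  for (f in per_frame) {
    expect_equal(unname(as.matrix(f)), unname(as.matrix(per_frame[[1]])))
  }
  expect_equal(length(unique(res$counts$n_cells)), 1)
})

test_that("blob tracks drift with the scene", {
  spec <- scene_spec(seed = 33, n_cells = 4, height = 128, width = 128)
  sq <- generate_sequence(spec, n_frames = 5, drift_px_per_frame = c(2, 0))
  dir <- write_frames(tempfile("frames"), sq$frames)
  out <- tempfile("run")
  res <- process_sequence(frame_source(dir),
                          run_config(output_dir = out, log_level = "quiet"),
                          write_segments = FALSE)
  b0 <- res$blobs[res$blobs$frame == 0, ]
  b4 <- res$blobs[res$blobs$frame == 4, ]
  # match frame-4 blobs to frame-0 blobs shifted by 4 * drift
  shifted <- transform(b0, x = (x + 8) %% spec$width)
  m <- match_detections(b4, transform(shifted, radius = 3), "radius")
  expect_gte(m$tp, nrow(b0) - 1)
})

test_that("per-frame outputs are independent of neighboring frames", {
  spec <- scene_spec(seed = 44, n_cells = 5, height = 96, width = 96)
  sq <- generate_sequence(spec, n_frames = 3, drift_px_per_frame = c(3, 2))
  dir_all <- write_frames(tempfile("frames"), sq$frames)
  dir_one <- write_frames(tempfile("frames"), sq$frames[2])

  out_all <- tempfile("run"); out_one <- tempfile("run")
  res_all <- process_sequence(frame_source(dir_all),
                              run_config(output_dir = out_all,
                                         log_level = "quiet"),
                              write_segments = FALSE)
  res_one <- process_sequence(frame_source(dir_one),
                              run_config(output_dir = out_one,
                                         log_level = "quiet"),
                              write_segments = FALSE)
  a <- res_all$blobs[res_all$blobs$frame == 1, c("x", "y", "sigma")]
  b <- res_one$blobs[, c("x", "y", "sigma")]
  expect_equal(unname(as.matrix(a)), unname(as.matrix(b)))
})
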