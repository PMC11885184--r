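test_that("extremum selection matches a brute-force 26-neighbor scan on random volumes", {
  set.seed(42)
  for (trial in 1:10) {
    vol <- array(runif(5 * 32 * 32), dim = c(32, 32, 5))
    ss <- structure(list(responses = vol, sigmas = 1:5, polarity = "dark"),
                    class = "scale_space")
    got <- find_scale_space_extrema(
      ss, detection_config(threshold_rel = 1e-9))
    got <- got[order(got$x, got$y, got$sigma), ]
    want <- brute_force_extrema(vol)
    expect_equal(got$x, as.numeric(want$x))
    expect_equal(got$y, as.numeric(want$y))
    expect_equal(got$sigma, as.numeric(want$s + 1))   # sigmas are 1..5
  }
})

test_that("constant images yield no detections", {
  blobs <- detect_blobs(matrix(0.6, 32, 32), sigma_schedule(2, 6, 5))
  expect_equal(nrow(blobs), 0)
})

test_that("a single dark spot is found at its center and scale, once", {
  sched <- sigma_schedule(1, 8, 12, "log")
  im <- render_spot(49, 24, 20, sigma = 4)
  blobs <- detect_blobs(im, sched)
  expect_equal(nrow(blobs), 1)
  expect_lte(abs(blobs$x - 24), 1)
  expect_lte(abs(blobs$y - 20), 1)
  expect_lte(abs(schedule_index(sched, blobs$sigma) -
                 schedule_index(sched, 4)), 1)
})

test_that("detections are covariant to translation", {
  sched <- sigma_schedule(1.5, 6, 8)
  a <- detect_blobs(render_spot(64, 25, 22, sigma = 3), sched)
  b <- detect_blobs(render_spot(64, 32, 27, sigma = 3), sched)
  expect_equal(nrow(a), 1); expect_equal(nrow(b), 1)
  expect_equal(b$x - a$x, 7)
  expect_equal(b$y - a$y, 5)
  expect_equal(a$sigma, b$sigma)
})

test_that("detections are covariant to 2x upsampling with a doubled schedule", {
  im <- render_spot(64, 30, 26, sigma = 3)
  s1 <- sigma_schedule(1.5, 6, 8)
  s2 <- sigma_schedule(3, 12, 8)
  a <- detect_blobs(im, s1)
  b <- detect_blobs(upsample2(im), s2)
  expect_equal(nrow(a), 1); expect_equal(nrow(b), 1)
  expect_lte(abs(b$x - 2 * a$x), 2)
  expect_lte(abs(b$y - 2 * a$y), 2)
  expect_lte(abs(schedule_index(s2, b$sigma) -
                 schedule_index(s2, 2 * a$sigma)), 1)
})

test_that("every blob satisfies the radius law r = sqrt(2) * sigma", {
  scene <- generate_scene(scene_spec(seed = 5, n_cells = 12))
  blobs <- detect_blobs(scene$gray)
  expect_gt(nrow(blobs), 0)
  expect_equal(blobs$radius, sqrt(2) * blobs$sigma, tolerance = 1e-12)
})

test_that("raising the relative threshold never adds blobs", {
  scene <- generate_scene(scene_spec(seed = 9))
  ss <- build_scale_space(scene$gray)
  prev <- NULL
  for (thr in c(0.05, 0.2, 0.5, 0.9)) {
    cur <- find_scale_space_extrema(ss, detection_config(threshold_rel = thr))
    if (!is.null(prev)) {
      key <- function(b) paste(b$x, b$y, b$sigma)
      expect_true(all(key(cur) %in% key(prev)))
    }
    prev <- cur
  }
})

test_that("fewer than 3 scale layers is rejected", {
  vol <- array(runif(2 * 16 * 16), dim = c(16, 16, 2))
  ss <- structure(list(responses = vol, sigmas = 1:2, polarity = "dark"),
                  class = "scale_space")
  expect_error(find_scale_space_extrema(ss), "3 scale layers")
})

test_that("pruning drops concentric duplicates and keeps disjoint discs", {
  b <- data.frame(x = c(10, 10), y = c(10, 10), sigma = c(3, 3),
                  radius = c(4.24, 4.24), response = c(1, 0.9),
                  polarity = "dark")
  kept <- prune_overlaps(b, 0.5)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$response, 1)

  b2 <- data.frame(x = c(10, 40), y = c(10, 40), sigma = c(3, 3),
                   radius = c(4.24, 4.24), response = c(1, 0.9),
                   polarity = "dark")
  expect_equal(nrow(prune_overlaps(b2, 0.5)), 2)
})

test_that("pruning of collinear equal-response discs follows the overlap oracle", {
  # radius-5 discs at x = 0, 6, 12: (0,6) overlap, (0,12) disjoint
  ov_near <- grid_circle_overlap(0, 0, 5, 6, 0, 5)
  ov_far <- grid_circle_overlap(0, 0, 5, 12, 0, 5)
  expect_gt(ov_near / (pi * 25), 0.05)
  expect_equal(ov_far, 0, tolerance = 1e-6)

  b <- data.frame(x = c(0, 6, 12), y = 0, sigma = 5 / sqrt(2), radius = 5,
                  response = 1, polarity = "dark")
  kept <- prune_overlaps(b, 0.05)
  expect_equal(kept$x, c(0, 12))   # tie broken by (y, x): x=0 kept first
})

test_that("the package's disc overlap area agrees with grid quadrature", {
  cases <- list(c(0, 0, 5, 6, 0, 5), c(0, 0, 4, 2, 1, 3),
                c(0, 0, 3, 0, 0, 5), c(0, 0, 2, 10, 0, 2))
  for (cs in cases) {
    a_pkg <- cytoblob:::circle_overlap_area(cs[1], cs[2], cs[3],
                                            cs[4], cs[5], cs[6])
    a_grid <- grid_circle_overlap(cs[1], cs[2], cs[3], cs[4], cs[5], cs[6])
    expect_equal(a_pkg, a_grid, tolerance = 0.01 + 0.01 * a_grid)
  }
})

test_that("detection is deterministic, byte-for-byte after serialization", {
  scene <- generate_scene(scene_spec(seed = 3, n_cells = 10))
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_blobs(detect_blobs(scene$gray), f1)
  write_blobs(detect_blobs(scene$gray), f2)
  expect_identical(readLines(f1), readLines(f2))
})
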