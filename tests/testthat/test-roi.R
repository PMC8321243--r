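test_that("average projection equals the per-pixel time mean", {
  # constant stack: projection equals any single frame
  const <- time_lapse_stack(array(7, c(4, 5, 3)), 1)
  expect_equal(unclass(average_projection(const)),
               matrix(7, 4, 5), ignore_attr = TRUE)

  # two frames with values 2 and 4 average to 3
  v <- array(c(rep(2, 12), rep(4, 12)), c(3, 4, 2))
  expect_true(all(unclass(average_projection(time_lapse_stack(v, 1))) == 3))

  # random stack vs element-wise brute-force loop
  set.seed(11)
  v <- array(stats::runif(8 * 8 * 5), c(8, 8, 5))
  stk <- time_lapse_stack(v, 1)
  p <- average_projection(stk)
  brute <- matrix(0, 8, 8)
  for (x in 1:8) for (y in 1:8) {
    acc <- 0
    for (t in 1:5) acc <- acc + v[x, y, t]
    brute[x, y] <- acc / 5
  }
  expect_equal(unclass(p), brute, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("average projection is linear in the stack", {
  set.seed(12)
  v1 <- array(stats::runif(60), c(4, 5, 3))
  v2 <- array(stats::runif(60), c(4, 5, 3))
  p12 <- average_projection(time_lapse_stack(2 * v1 + 3 * v2, 1))
  p1 <- average_projection(time_lapse_stack(v1, 1))
  p2 <- average_projection(time_lapse_stack(v2, 1))
  expect_equal(unclass(p12), 2 * unclass(p1) + 3 * unclass(p2),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("a uniform image yields no ROIs", {
  p <- matrix(5, 32, 32)
  rois <- detect_rois(p, prominence = 1, tolerance = 1, pixel_size_um = 1)
  expect_equal(nrow(rois), 0L)
})

test_that("two planted Gaussians are recovered with sub-pixel centroids", {
  blobs <- data.frame(x = c(20.3, 60.7), y = c(25.2, 55.5),
                      radius_um = c(5, 5), peak = c(800, 800))
  stk <- simulate_image_stack(blobs, 2, dim = c(96, 96), pixel_size_um = 1,
                              noise_sd = 0, seed = 1)
  rois <- detect_rois(average_projection(stk), prominence = 200,
                      tolerance = 400)
  expect_equal(nrow(rois), 2L)
  ord <- order(rois$centroid_x)
  expect_true(all(abs(rois$centroid_x[ord] - blobs$x) <= 1))
  expect_true(all(abs(rois$centroid_y[ord] - blobs$y) <= 1))
})

test_that("the size filter is a strict post-filter", {
  set.seed(13)
  pts <- random_blob_layout(8, 25, 175, 40)
  blobs <- data.frame(x = pts[, 1], y = pts[, 2],
                      radius_um = stats::runif(8, 4, 20), peak = 1000)
  stk <- simulate_image_stack(blobs, 2, dim = c(200, 200),
                              pixel_size_um = 1, noise_sd = 0, seed = 2)
  p <- average_projection(stk)
  filtered <- detect_rois(p, 300, 500, max_linear_size_um = 30)
  unfiltered <- detect_rois(p, 300, 500, max_linear_size_um = Inf)
  expect_gte(nrow(unfiltered), nrow(filtered))
  expect_true(all(filtered$size_um <= 30))
})

test_that("extract_traces reproduces per-ROI means", {
  set.seed(14)
  v <- array(stats::runif(10 * 10 * 6), c(10, 10, 6))
  stk <- time_lapse_stack(v, 1)
  # hand-built ROI set: one single-pixel ROI and one 4-pixel ROI
  rois <- data.frame(id = 1:2, centroid_x = c(3, 7), centroid_y = c(4, 7),
                     area_px = c(1L, 4L), size_um = c(1, 2),
                     peak = c(0, 0))
  px1 <- (4 - 1) * 10 + 3               # pixel (3, 4)
  px2 <- c((7 - 1) * 10 + 7, (7 - 1) * 10 + 8,
           (8 - 1) * 10 + 7, (8 - 1) * 10 + 8)  # 2x2 block at (7:8, 7:8)
  attr(rois, "pixels") <- list(px1, px2)
  class(rois) <- c("roi_set", "data.frame")
  tr <- extract_traces(stk, rois)

  expect_equal(unclass(tr)[, 1], v[3, 4, ], ignore_attr = TRUE)
  brute <- sapply(1:6, function(t) {
    mean(c(v[7, 7, t], v[8, 7, t], v[7, 8, t], v[8, 8, t]))
  })
  expect_equal(unclass(tr)[, 2], brute, ignore_attr = TRUE,
               tolerance = 1e-12)

  # constant stack: every trace is constant
  cstk <- time_lapse_stack(array(3, c(10, 10, 4)), 1)
  ctr <- extract_traces(cstk, rois)
  expect_true(all(unclass(ctr) == 3))

  # zero-pixel ROI rejected
  attr(rois, "pixels") <- list(px1, integer(0))
  expect_error(extract_traces(stk, rois), "zero pixels")
})

test_that("detection composed with extraction recovers planted intensity
           schedules", {
  set.seed(15)
  pts <- random_blob_layout(4, 30, 130, 45)
  blobs <- data.frame(x = pts[, 1], y = pts[, 2], radius_um = 6,
                      peak = 1000)
  # per-blob, per-frame intensity schedules
  fs <- outer(seq(1, 1.5, length.out = 8), stats::runif(4, 0.8, 1.2))
  stk <- simulate_image_stack(blobs, 8, dim = c(160, 160),
                              pixel_size_um = 1, noise_sd = 0,
                              frame_scale = fs, seed = 3)
  rois <- detect_rois(average_projection(stk), 200, 450)
  expect_equal(nrow(rois), 4L)
  tr <- extract_traces(stk, rois)
  # each trace proportional to its blob's schedule column
  for (i in seq_len(4)) {
    b <- which.min((blobs$x - rois$centroid_x[i])^2 +
                     (blobs$y - rois$centroid_y[i])^2)
    ratio <- unclass(tr)[, i] / fs[, b]
    expect_lt(stats::sd(ratio) / mean(ratio), 1e-10)
  }
})

test_that("channel alignment recovers integer shifts", {
  set.seed(16)
  pts <- random_blob_layout(5, 20, 100, 30)
  blobs <- data.frame(x = pts[, 1], y = pts[, 2], radius_um = 5,
                      peak = 100)
  a <- simulate_image_stack(blobs, 2, dim = c(128, 128), pixel_size_um = 1,
                            noise_sd = 0, seed = 4)
  expect_equal(align_channels(a, a, 4), c(0L, 0L))

  shifted <- data.frame(x = pts[, 1] + 2, y = pts[, 2] + 1,
                        radius_um = 5, peak = 100)
  b <- simulate_image_stack(shifted, 2, dim = c(128, 128),
                            pixel_size_um = 1, noise_sd = 0, seed = 4)
  expect_equal(align_channels(a, b, 4), c(2L, 1L))
  # undoing the shift restores near-perfect correlation
  b_fixed <- shift_stack(b, c(2L, 1L))
  expect_equal(align_channels(a, b_fixed, 4), c(0L, 0L))

  # uncorrelated noise: contract only — a shift within bounds, no failure
  n1 <- time_lapse_stack(array(stats::rnorm(64 * 64 * 2)^2, c(64, 64, 2)), 1)
  n2 <- time_lapse_stack(array(stats::rnorm(64 * 64 * 2)^2, c(64, 64, 2)), 1)
  sh <- align_channels(n1, n2, 3)
  expect_true(all(abs(sh) <= 3))
})
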