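test_that("the frontal view is the identity on pixels and coordinates", {
  img <- blob_image(96, 3, seed = 2)$image
  v <- simulate_view(img, tilt = 1, phi = 0)
  expect_identical(v$image, img)
  expect_equal(unclass(v$to_view), cbind(diag(2), c(0, 0)),
               ignore_attr = TRUE)
  expect_equal(v$antialias_sigma, 0)
})

test_that("a pure tilt halves the compressed axis and records the blur", {
  img <- matrix(runif(512 * 512) * 255, 512)
  v <- simulate_view(img, tilt = 2, phi = 0)
  expect_equal(ncol(v$image), 256)
  expect_equal(nrow(v$image), 512)
  expect_equal(v$antialias_sigma, 0.8 * sqrt(3), tolerance = 1e-12)
})

test_that("view transforms are exact inverses on the frame corners", {
  img <- matrix(runif(256 * 256) * 255, 256)
  for (pose in list(c(sqrt(2), 0.9), c(2, 2.2), c(2 * sqrt(2), 0.3))) {
    v <- simulate_view(img, pose[1], pose[2])
    corners <- cbind(c(0, 255, 0, 255), c(0, 0, 255, 255))
    back <- transform_points(v$from_view, transform_points(v$to_view, corners))
    expect_lt(max(abs(back - corners)), 1e-6)
    id <- compose_transforms(v$to_view, v$from_view)
    expect_equal(unclass(id), cbind(diag(2), c(0, 0)), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("degenerate simulated views are refused", {
  expect_error(simulate_view(matrix(1, 10, 10), tilt = 2 * sqrt(2)),
               "degenerates")
})

test_that("backprojection maps view keypoints to original coordinates", {
  img <- blob_image(128, 5, seed = 9)$image
  v <- simulate_view(img, tilt = 2, phi = 0.7)
  # a fabricated keypoint at the view image of the original point (100, 90)
  pv <- transform_points(v$to_view, cbind(100, 90))
  det <- list(keypoints = data.frame(x = pv[1], y = pv[2], scale = 2,
                                     orientation = 0, response = 1),
              descriptors = matrix(1, 1, 8), metric = "euclidean")
  back <- backproject_keypoints(det, v, dim(img))
  expect_equal(c(back$keypoints$x, back$keypoints$y), c(100, 90),
               tolerance = 1e-6)
  # identity view leaves keypoints alone
  v0 <- simulate_view(img, 1, 0)
  det0 <- det
  det0$keypoints$x <- 100; det0$keypoints$y <- 90
  back0 <- backproject_keypoints(det0, v0, dim(img))
  expect_equal(c(back0$keypoints$x, back0$keypoints$y), c(100, 90))
  # a keypoint backprojecting out of bounds is dropped with its descriptor
  pv_out <- transform_points(v$to_view, cbind(-5, 40))
  det$keypoints$x <- pv_out[1]; det$keypoints$y <- pv_out[2]
  gone <- backproject_keypoints(det, v, dim(img))
  expect_identical(nrow(gone$keypoints), 0L)
  expect_identical(nrow(gone$descriptors), 0L)
})
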