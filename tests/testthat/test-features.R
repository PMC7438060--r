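test_that("a constant image yields no keypoints for any backend", {
  flat <- matrix(128, 96, 96)
  for (be in all_backends) {
    det <- detect_and_describe(flat, be)
    expect_identical(nrow(det$keypoints), 0L, label = be)
    expect_identical(nrow(det$descriptors), 0L, label = be)
  }
})

test_that("detection is deterministic", {
  img <- blob_image(128, 6, seed = 4)$image
  for (be in all_backends) {
    d1 <- detect_and_describe(img, be)
    d2 <- detect_and_describe(img, be)
    expect_identical(d1$keypoints, d2$keypoints, label = be)
    expect_identical(d1$descriptors, d2$descriptors, label = be)
  }
})

test_that("every backend localizes at least one synthetic blob center", {
  fx <- blob_image(256, 10, seed = 1)
  for (be in all_backends) {
    det <- detect_and_describe(fx$image, be)
    expect_gt(nrow(det$keypoints), 0, label = be)
    # keypoints are 0-based, fixture centers 1-based
    d <- sqrt(outer(det$keypoints$x + 1, fx$centers[, 1], "-")^2 +
                outer(det$keypoints$y + 1, fx$centers[, 2], "-")^2)
    expect_lt(min(d), 3, label = be)
  }
})

test_that("metric tags follow the backend family", {
  img <- blob_image(96, 4, seed = 5)$image
  expect_identical(detect_and_describe(img, "SIFT")$metric, "euclidean")
  expect_identical(detect_and_describe(img, "SURF")$metric, "euclidean")
  for (be in c("AKAZE", "BRISK", "ORB")) {
    det <- detect_and_describe(img, be)
    expect_identical(det$metric, "hamming", label = be)
    expect_true(is.raw(det$descriptors), label = be)
  }
})

test_that("the ORB feature budget caps detections", {
  img <- blob_image(256, 10, seed = 1)$image
  det <- detect_and_describe(img, "ORB", n_features = 50)
  expect_lte(nrow(det$keypoints), 50)
})

test_that("unknown backends and undersized images are refused", {
  img <- blob_image(96, 3, seed = 6)$image
  expect_error(detect_and_describe(img, "KAZE"), "unknown backend")
  expect_error(detect_and_describe(matrix(0, 16, 16), "SIFT"), "too small")
})

test_that("descriptor rows track keypoint rows", {
  img <- blob_image(160, 8, seed = 8)$image
  for (be in all_backends) {
    det <- detect_and_describe(img, be)
    expect_identical(nrow(det$descriptors), nrow(det$keypoints), label = be)
    expect_true(all(det$keypoints$scale > 0), label = be)
    expect_true(all(is.finite(det$keypoints$x)), label = be)
  }
})
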