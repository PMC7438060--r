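test_that("the 60-pixel ROI filter keeps the boundary case and drops below it", {
  lab <- matrix(0L, 64, 64)
  lab[2:60, 2] <- 1L          # 59 px
  lab[10:19, 10:15] <- 2L     # 60 px
  rm_ <- binarize_and_filter(lab, min_pixels = 60)
  expect_identical(length(rm_$rois), 1L)
  expect_identical(nrow(rm_$rois[[1]]), 60L)
  expect_identical(sum(rm_$image > 0), 60L)
  expect_true(all(rm_$image %in% c(0, 255)))
})

test_that("an empty mask yields an empty ROI set", {
  rm_ <- binarize_and_filter(matrix(0L, 32, 32))
  expect_identical(length(rm_$rois), 0L)
  expect_identical(nrow(rm_$centroids), 0L)
  expect_true(all(rm_$image == 0))
})

test_that("binary input is relabelled by 8-connectivity and pixel sets tile the foreground", {
  scene <- generate_scene(20, c(256, 256), seed = 3)
  mask <- render_session(scene, seed = 2)$mask
  expect_identical(length(mask$rois), 20L)
  expect_true(all(vapply(mask$rois, nrow, 0L) >= 60))
  all_px <- do.call(rbind, mask$rois)
  expect_identical(nrow(all_px), sum(mask$image > 0))
  # diagonal contact is one component under 8-connectivity
  diagm <- matrix(0L, 40, 40)
  diagm[5:12, 5:12] <- 1L
  diagm[13:20, 13:20] <- 1L
  rm2 <- binarize_and_filter(diagm, min_pixels = 60)
  expect_identical(length(rm2$rois), 1L)
})

test_that("binarize_and_filter is idempotent", {
  scene <- generate_scene(8, c(128, 128), seed = 5)
  m1 <- render_session(scene, seed = 2)$mask
  m2 <- binarize_and_filter(m1$image)
  expect_identical(m1$image, m2$image)
  expect_equal(m1$centroids, m2$centroids)
})

test_that("mask correlation matches the closed-form Pearson values", {
  a <- matrix(c(255, 0, 0, 0), 2)
  b <- matrix(c(0, 0, 255, 0), 2)
  expect_equal(mask_correlation(a, b), -1 / 3)
  m <- matrix(0, 8, 8); m[2:4, 2:4] <- 255
  expect_equal(mask_correlation(m, m), 1)
  expect_error(mask_correlation(matrix(0, 8, 8), m), "constant")
})

test_that("mask correlation is symmetric and encoding-invariant", {
  set.seed(9)
  a <- matrix(255 * (runif(256) > 0.8), 16)
  b <- matrix(255 * (runif(256) > 0.8), 16)
  expect_equal(mask_correlation(a, b), mask_correlation(b, a))
  expect_equal(mask_correlation(a, b), mask_correlation(a / 255, b / 255))
})

test_that("sharpness has its closed-form values on constant and impulse images", {
  const <- matrix(5, 32, 32)
  expect_equal(sharpness(const, const)$value, 1 / (32 * 32))
  imp <- matrix(0, 32, 32); imp[17, 17] <- 1
  expect_equal(sharpness(imp, imp)$value, 1)
  r <- sharpness(const, const)
  expect_equal(r$threshold, r$template_max_M / 1000)
})

test_that("sharpness decreases strictly with blur and is scale-invariant", {
  img <- blob_image(128, 8, seed = 13)$image
  vals <- vapply(c(0, 1, 2, 4), function(s) {
    blurred <- if (s > 0) fovalign:::cpp_gauss_blur(img, s, s) else img
    sharpness(blurred, img)$value
  }, 0)
  expect_true(all(diff(vals) < 0))
  expect_equal(sharpness(img, img)$value, sharpness(img * 3, img * 3)$value)
})

test_that("common-neuron counting pairs ROIs through the true transform", {
  scene <- generate_scene(15, c(192, 192), seed = 17)
  m <- render_session(scene, seed = 4)$mask
  full <- count_common_neurons(m, m)
  expect_identical(full$count, 15L)
  # disjoint, far-separated sets pair nothing
  far <- binarize_and_filter({
    x <- matrix(0L, 192, 192); x[5:14, 5:12] <- 1L; x
  })
  expect_identical(count_common_neurons(far, {
    y <- matrix(0L, 192, 192); y[150:159, 150:157] <- 1L
    binarize_and_filter(y)
  })$count, 0L)
})

test_that("a known shared subset is recovered exactly", {
  scene <- generate_scene(24, c(224, 224), seed = 23)
  s1 <- render_session(scene, active_fraction = 0.7, seed = 31)
  s2 <- render_session(scene,
                       pose = affine_pose(psi = 0.1, tilt = 1.1, phi = 0.3),
                       translation = c(6, -3), active_fraction = 0.7,
                       seed = 32)
  shared <- intersect(s1$active_indices, s2$active_indices)
  rel <- compose_transforms(s2$true_transform,
                            invert_transform(s1$true_transform))
  got <- count_common_neurons(s1$mask, s2$mask, rel)
  expect_identical(got$count, length(shared))
})
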