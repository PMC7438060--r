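test_that("the L1 mask score is the symmetric-difference mass", {
  m <- matrix(0, 64, 64)
  m[10:19, 10:19] <- 255
  expect_equal(l1_mask_score(affine_transform(), m, m), 0)
  # disjoint masks of 100 and 80 foreground pixels under the identity
  a <- matrix(0, 64, 64); a[1:10, 1:10] <- 255
  b <- matrix(0, 64, 64); b[40:49, 40:47] <- 255
  expect_equal(sum(a > 0), 100)
  expect_equal(sum(b > 0), 80)
  expect_equal(l1_mask_score(affine_transform(), a, b), 255 * 180)
})

test_that("the true transform scores no worse than the identity on a clean pair", {
  p <- tiny_pair(seed = 21, blur = 0, noise = 0, background = 0)
  s_true <- l1_mask_score(p$true_transform, p$moving$mask$image,
                          p$template$mask$image)
  s_id <- l1_mask_score(affine_transform(), p$moving$mask$image,
                        p$template$mask$image)
  expect_lte(s_true, s_id)
})

test_that("apply_transform warps as promised", {
  m <- matrix(0, 32, 32)
  expect_identical(apply_transform(affine_transform(), m + 7), m + 7)
  # a single-pixel mask moves 10 columns under a pure translation
  px <- matrix(0, 32, 32); px[15, 5] <- 255
  w <- apply_transform(affine_transform(e = 10), px, "nearest")
  expect_equal(which(w == 255, arr.ind = TRUE)[1, ], c(row = 15, col = 15))
  expect_error(apply_transform(affine_transform(a = 0, d = 0), m), "invertible")
})

test_that("a warp round-trip preserves at least 95 percent of large ROIs", {
  scene <- generate_scene(12, c(160, 160), seed = 31)
  mask <- render_session(scene, seed = 1)$mask$image
  # rotation/tilt anchored at the frame centre so content stays in frame
  l <- compose_affine(affine_pose(psi = 0.25, tilt = 1.15, phi = 0.4))
  ctr <- c(79.5, 79.5)
  tr <- as_affine_transform(cbind(unclass(l)[, 1:2],
                                  ctr - unclass(l)[, 1:2] %*% ctr + c(7.3, -4.2)))
  there <- apply_transform(tr, mask, "nearest")
  back <- apply_transform(invert_transform(tr), there, "nearest")
  expect_gte(sum(back > 0 & mask > 0) / sum(mask > 0), 0.95)
})

test_that("CLAHE is range-preserving, fixes nothing on a constant image, and lifts low contrast", {
  flat <- matrix(100, 64, 64)
  out <- clahe_preprocess(flat)
  expect_equal(max(out) - min(out), 0)
  set.seed(5)
  noisy <- matrix(runif(128 * 128, 0, 255), 128)
  o2 <- clahe_preprocess(noisy)
  expect_gte(min(o2), 0)
  expect_lte(max(o2), 255)
  low <- matrix(runif(128 * 128, 100, 130), 128)
  expect_gt(sd(clahe_preprocess(low)), sd(low))
})

test_that("aligning an image to itself recovers the identity with L1 zero", {
  p <- tiny_pair(seed = 41)
  tpl <- p$template
  r <- align_fov(tpl$image, tpl$image, tpl$mask$image, tpl$mask$image,
                 backend = "SIFT", n_repeats = 5, seed = 3,
                 max_tilt_index = 2)
  expect_lt(corner_error(r$transform, affine_transform(), dim(tpl$image)), 0.5)
  expect_equal(min(r$l1_scores), 0)
  expect_equal(r$l1_scores[r$selected_repeat], min(r$l1_scores))
})

test_that("alignment recovers a known session pose", {
  p <- tiny_pair(seed = 51, tilt_deg = 30, spin_deg = 10,
                 translation = c(15, -8), blur = 1.5)
  r <- align_fov(p$moving$image, p$template$image, p$moving$mask$image,
                 p$template$mask$image, backend = "SIFT", n_repeats = 10,
                 seed = 1, max_tilt_index = 3)
  expect_lt(corner_error(r$transform, p$true_transform, dim(p$moving$image)), 2)
  expect_equal(r$inlier_ratio, r$n_inliers / r$n_matched)
  expect_identical(length(r$l1_scores), 10L)
  expect_identical(r$repeat_seeds, 1 + 0:9)
})

test_that("alignment is bit-identical under a fixed seed", {
  p <- tiny_pair(seed = 61)
  run <- function() align_fov(p$moving$image, p$template$image,
                              p$moving$mask$image, p$template$mask$image,
                              backend = "ORB", n_repeats = 6, seed = 11,
                              max_tilt_index = 2)
  r1 <- run(); r2 <- run()
  expect_identical(r1, r2)
})

test_that("featureless images cannot be aligned", {
  a <- matrix(12, 96, 96)   # constant: no keypoints anywhere
  b <- matrix(40, 96, 96)
  ma <- matrix(0, 96, 96); ma[10:19, 10:19] <- 255
  expect_error(
    align_fov(a, b, ma, ma, backend = "SIFT", n_repeats = 3, seed = 1,
              max_tilt_index = 1),
    "matches|keypoints|align")
})

test_that("the winning repeat is the arg-min of the L1 scores", {
  p <- tiny_pair(seed = 81)
  r <- align_fov(p$moving$image, p$template$image, p$moving$mask$image,
                 p$template$mask$image, backend = "BRISK", n_repeats = 8,
                 seed = 2, max_tilt_index = 2)
  expect_true(all(r$l1_scores[r$selected_repeat] <= r$l1_scores))
})
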