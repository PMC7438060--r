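test_that("scenes are reproducible, spaced, and sized for the ROI filter", {
  s1 <- generate_scene(20, c(512, 512), seed = 7)
  s2 <- generate_scene(20, c(512, 512), seed = 7)
  expect_identical(s1, s2)
  d <- as.matrix(dist(s1$neuron_centers))
  diag(d) <- Inf
  expect_gte(min(d), 12)
  # every noiseless frontal ROI passes the 60 px filter by construction
  mask <- render_session(s1, seed = 1)$mask
  expect_identical(length(mask$rois), 20L)
  expect_true(all(vapply(mask$rois, nrow, 0L) >= 60))
})

test_that("infeasible densities fail after bounded attempts", {
  expect_error(generate_scene(4000, c(128, 128), seed = 1), "spacing|place")
})

test_that("a noiseless identity render reproduces the scene geometry", {
  scene <- generate_scene(15, c(256, 256), seed = 3)
  r <- render_session(scene, seed = 5)
  expect_identical(length(r$mask$rois), 15L)
  got <- r$mask$centroids[order(r$mask$centroids[, 1]), ]
  want <- scene$neuron_centers[order(scene$neuron_centers[, 1]), ]
  expect_lt(max(abs(got - want)), 0.5)
  expect_true(all(r$image >= 0 & r$image <= 255))
  expect_identical(r$image, round(r$image))  # 8-bit quantized
})

test_that("active_fraction selects the expected subset size and is bookkept", {
  scene <- generate_scene(20, c(256, 256), seed = 11)
  r <- render_session(scene, active_fraction = 0.5, seed = 9)
  expect_identical(length(r$active_indices), 10L)
  expect_identical(length(r$mask$rois), 10L)
  r1 <- render_session(scene, active_fraction = 0.7, seed = 100)
  r2 <- render_session(scene, active_fraction = 0.7, seed = 200)
  expect_identical(length(r1$active_indices), 14L)
  expect_identical(length(r1$mask$rois), 14L)
  shared <- intersect(r1$active_indices, r2$active_indices)
  expect_true(all(shared %in% seq_len(20)))
  expect_lt(length(shared), 14L)  # independent subsets differ
})

test_that("warping the frontal mask by the ground-truth transform reproduces the render's mask", {
  scene <- generate_scene(18, c(256, 256), seed = 13)
  frontal <- render_session(scene, seed = 21)
  tilted <- render_session(scene,
                           pose = affine_pose(psi = 0.15, tilt = 1.25,
                                              phi = 0.8),
                           translation = c(8, 5), seed = 21)
  rel <- compose_transforms(tilted$true_transform,
                            invert_transform(frontal$true_transform))
  warped <- apply_transform(rel, frontal$mask$image, "nearest")
  refiltered <- binarize_and_filter(warped)
  inter <- sum(refiltered$image > 0 & tilted$mask$image > 0)
  expect_gte(inter / sum(tilted$mask$image > 0), 0.95)
})

test_that("the benchmark suite is deterministic, stratified and degradation-ordered", {
  cfg <- benchmark_config(n_pairs_easy = 2, n_pairs_stress = 2,
                          n_neurons = 24)
  s1 <- benchmark_suite(cfg, seed = 0)
  s2 <- benchmark_suite(cfg, seed = 0)
  expect_identical(length(s1), 4L)
  expect_identical(vapply(s1, `[[`, "", "stratum"),
                   c("easy", "easy", "stress", "stress"))
  expect_identical(s1[[3]]$moving$image, s2[[3]]$moving$image)
  for (p in s1) {
    expect_gt(transform_det(p$true_transform), 0)
    expect_true(all(p$shared_indices %in% p$template$active_indices))
    expect_true(all(p$shared_indices %in% p$moving$active_indices))
  }
})

test_that("stress pairs start less correlated than easy pairs", {
  cfg <- benchmark_config(n_pairs_easy = 3, n_pairs_stress = 3,
                          n_neurons = 24)
  suite <- benchmark_suite(cfg, seed = 1)
  pre <- vapply(suite, function(p) {
    cm <- pair_common_masks(p)
    mask_correlation(cm$moving, cm$template)
  }, 0)
  strata <- vapply(suite, `[[`, "", "stratum")
  expect_lt(mean(pre[strata == "stress"]), mean(pre[strata == "easy"]))
})
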