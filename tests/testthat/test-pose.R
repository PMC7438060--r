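test_that("composing the frontal pose gives the identity, a pure tilt stretches one axis", {
  id <- compose_affine(affine_pose(lambda_zoom = 1, psi = 0, tilt = 1, phi = 0))
  expect_equal(unclass(id), cbind(diag(2), c(0, 0)), tolerance = 1e-12,
               ignore_attr = TRUE)
  m <- compose_affine(affine_pose(tilt = 2, phi = 0))
  expect_equal(linear_part <- unclass(m)[, 1:2], diag(c(2, 1)),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_gt(transform_det(m), 0)
})

test_that("decomposition recovers canonical poses from plain matrices", {
  p <- decompose_affine(diag(2))
  expect_equal(p$lambda_zoom, 1, tolerance = 1e-12)
  expect_equal(p$tilt, 1, tolerance = 1e-12)
  expect_equal(p$psi, 0, tolerance = 1e-12)
  expect_equal(p$phi, 0, tolerance = 1e-12)
  p2 <- decompose_affine(diag(c(2, 1)))
  expect_equal(p2$tilt, 2, tolerance = 1e-10)
  expect_equal(p2$lambda_zoom, 1, tolerance = 1e-10)
  expect_equal(p2$psi, 0, tolerance = 1e-10)
  expect_equal(p2$phi, 0, tolerance = 1e-10)
  expect_equal(p2$theta, acos(1 / 2), tolerance = 1e-10)
})

test_that("negative-determinant maps are rejected with the determinant named", {
  expect_error(decompose_affine(diag(c(-1, 1))), "determinant")
})

test_that("compose/decompose round-trips random positive-determinant maps", {
  set.seed(42)
  worst <- 0
  for (i in 1:300) {
    m <- random_posdet_matrix()
    m2 <- unclass(compose_affine(decompose_affine(m)))[, 1:2]
    worst <- max(worst, max(abs(m - m2)))
  }
  expect_lt(worst, 1e-8)
})

test_that("pose angles are recovered modulo the joint flip equivalence", {
  set.seed(7)
  for (i in 1:100) {
    p <- affine_pose(lambda_zoom = runif(1, 0.5, 2), psi = runif(1, 0, 2 * pi),
                     tilt = runif(1, 1.05, 6), phi = runif(1, 0, pi))
    q <- decompose_affine(compose_affine(p))
    expect_equal(q$lambda_zoom, p$lambda_zoom, tolerance = 1e-8)
    expect_equal(q$tilt, p$tilt, tolerance = 1e-8)
    expect_equal(q$phi, p$phi, tolerance = 1e-6)
    expect_lt(min(abs(q$psi - p$psi), abs(abs(q$psi - p$psi) - 2 * pi)), 1e-6)
    expect_equal(cos(q$theta) * q$tilt, 1, tolerance = 1e-12)
  }
})

test_that("the tilt/longitude grid follows the 72-degrees-over-t rule", {
  expect_identical(nrow(sample_pose_grid(0)), 1L)
  expect_equal(sample_pose_grid(0)$tilt, 1)
  g <- sample_pose_grid(5)
  t2 <- g[abs(g$tilt - 2) < 1e-12, ]
  expect_equal(t2$phi * 180 / pi, c(0, 36, 72, 108, 144), tolerance = 1e-10)
  # brute-force enumeration oracle (strict inequality on exact reals, so
  # the floating-point comparison carries a boundary guard)
  count <- 0
  for (k in 0:5) {
    t_k <- 2^(k / 2)
    if (k == 0) count <- count + 1
    else count <- count + sum((0:1000) * (72 / t_k) < 180 - 1e-9)
  }
  expect_identical(nrow(g), as.integer(count))
  # deterministic, duplicate-free, every step exactly 72/t degrees
  expect_identical(g, sample_pose_grid(5))
  expect_false(any(duplicated(g)))
  for (t_k in unique(g$tilt[g$tilt > 1])) {
    phis <- g$phi[g$tilt == t_k] * 180 / pi
    expect_equal(diff(phis), rep(72 / t_k, length(phis) - 1), tolerance = 1e-10)
  }
  expect_true(all(diff(g$tilt) >= -1e-12))
})

test_that("pose validation enforces tilt and zoom ranges", {
  expect_error(affine_pose(tilt = 0.5))
  expect_error(affine_pose(lambda_zoom = -1))
  expect_error(sample_pose_grid(9))
})
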