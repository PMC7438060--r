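test_that("transform algebra: inversion, composition, point mapping", {
  set.seed(3)
  for (i in 1:50) {
    m <- random_posdet_matrix()
    tr <- as_affine_transform(cbind(m, rnorm(2, 0, 20)))
    inv <- invert_transform(tr)
    both <- compose_transforms(inv, tr)
    expect_equal(unclass(both), cbind(diag(2), c(0, 0)), tolerance = 1e-9,
                 ignore_attr = TRUE)
    pts <- matrix(runif(10, -50, 50), ncol = 2)
    expect_equal(transform_points(inv, transform_points(tr, pts)), pts,
                 tolerance = 1e-9)
  }
})

test_that("singular transforms are refused", {
  expect_error(invert_transform(affine_transform(a = 0, d = 0)), "invertible")
})

test_that("corner error measures mean frame-corner displacement", {
  shift <- affine_transform(e = 3, f = 4)
  expect_equal(corner_error(shift, affine_transform(), c(512, 512)), 5)
  expect_equal(corner_error(shift, shift, c(512, 512)), 0)
})
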