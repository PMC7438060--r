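# brute-force two-nearest-neighbour oracle, independent of the C++ path
nndr_oracle <- function(a, b, metric, ratio = 0.75) {
  dist1 <- function(u, v) {
    if (metric == "euclidean") sqrt(sum((u - v)^2))
    else sum(as.integer(xor(rawToBits(u), rawToBits(v))))
  }
  out <- NULL
  for (i in seq_len(nrow(a))) {
    d <- vapply(seq_len(nrow(b)), function(j) dist1(a[i, ], b[j, ]), 0)
    o <- order(d)
    r <- if (d[o[2]] > 0) d[o[1]] / d[o[2]] else if (d[o[1]] > 0) 1 else 0
    if (r < ratio) out <- rbind(out, c(i, o[1], d[o[1]], r))
  }
  if (is.null(out)) out <- matrix(numeric(0), 0, 4)
  colnames(out) <- c("idx_a", "idx_b", "distance", "ratio")
  out
}

test_that("the ratio test keeps unambiguous matches and drops ambiguous ones", {
  b <- rbind(c(1, 0, 0), c(0, 1, 0))
  # exact duplicate of b's first row: ratio 0, kept
  m <- match_nndr(rbind(c(1, 0, 0)), b)
  expect_identical(nrow(m), 1L)
  expect_identical(m$idx_b, 1L)
  expect_equal(m$ratio, 0)
  # d1/d2 = 0.8: rejected at the 0.75 threshold
  v <- rbind(c(0.8, 0.2, 0))
  b2 <- rbind(c(0.8, 0.2, 0.4), c(0.8, 0.2, 0.5))
  d <- c(0.4, 0.5)
  expect_equal(d[1] / d[2], 0.8)
  expect_identical(nrow(match_nndr(v, b2)), 0L)
  expect_identical(nrow(match_nndr(v, b2, ratio_threshold = 0.81)), 1L)
})

test_that("NNDR equals the exhaustive oracle for float and binary descriptors", {
  set.seed(11)
  a <- matrix(runif(60 * 16), 60)
  b <- matrix(runif(80 * 16), 80)
  got <- match_nndr(a, b)
  want <- nndr_oracle(a, b, "euclidean")
  expect_equal(nrow(got), nrow(want))
  expect_equal(got$idx_b, as.integer(want[, "idx_b"]))
  expect_equal(got$ratio, unname(want[, "ratio"]), tolerance = 1e-12)

  ra <- matrix(as.raw(sample(0:255, 50 * 8, TRUE)), 50)
  rb <- matrix(as.raw(sample(0:255, 70 * 8, TRUE)), 70)
  goth <- match_nndr(ra, rb)
  wanth <- nndr_oracle(ra, rb, "hamming")
  expect_equal(nrow(goth), nrow(wanth))
  expect_equal(goth$idx_b, as.integer(wanth[, "idx_b"]))
})

test_that("NNDR matches are invariant under permutation of the b side", {
  set.seed(12)
  a <- matrix(runif(40 * 8), 40)
  b <- matrix(runif(60 * 8), 60)
  perm <- sample(60)
  m1 <- match_nndr(a, b)
  m2 <- match_nndr(a, b[perm, ])
  expect_identical(m1$idx_a, m2$idx_a)
  expect_identical(as.integer(perm[m2$idx_b]), m1$idx_b)
  expect_equal(m1$distance, m2$distance, tolerance = 1e-12)
})

test_that("metric and shape mismatches are refused, as is a 1-row b side", {
  a <- matrix(runif(8), 2)
  expect_error(match_nndr(a, matrix(as.raw(1:8), 2)), "metric")
  expect_error(match_nndr(a, matrix(runif(6), 2)), "width")
  expect_error(match_nndr(a, matrix(runif(4), 1)), "at least 2")
})

test_that("RANSAC recovers an exact affine from 3 points and refuses 2", {
  tr <- matrix(c(1.2, 0.1, -0.3, 0.9, 15, -8), 2, 3)
  pa <- rbind(c(0, 0), c(100, 10), c(30, 200))
  pb <- t(tr[, 1:2] %*% t(pa) + tr[, 3])
  fit <- estimate_transform_ransac(pa, pb, seed = 5)
  expect_lt(max(abs(unclass(fit$transform) - tr)), 1e-6)
  expect_identical(fit$n_inliers, 3L)
  expect_error(estimate_transform_ransac(pa[1:2, ], pb[1:2, ]), "at least 3")
})

test_that("exact inlier sets are recovered regardless of seed", {
  set.seed(20)
  tr <- matrix(c(0.95, -0.2, 0.2, 1.05, 4, 9), 2, 3)
  pa <- cbind(runif(40, 0, 500), runif(40, 0, 500))
  pb <- t(tr[, 1:2] %*% t(pa) + tr[, 3])
  for (s in c(1, 99, 12345)) {
    fit <- estimate_transform_ransac(pa, pb, seed = s)
    expect_lt(max(abs(unclass(fit$transform) - tr)), 1e-9)
    expect_true(all(fit$inliers))
  }
})

test_that("RANSAC separates noisy inliers from gross outliers", {
  mk <- function(seed) {
    set.seed(seed)
    tr <- matrix(c(cos(0.2) * 1.05, sin(0.2), -sin(0.2), cos(0.2) * 0.95,
                   20, -12), 2, 3)
    pa_in <- cbind(runif(60, 20, 490), runif(60, 20, 490))
    pb_in <- t(tr[, 1:2] %*% t(pa_in) + tr[, 3]) +
      matrix(rnorm(120, 0, 0.3), ncol = 2)
    pa_out <- cbind(runif(40, 0, 512), runif(40, 0, 512))
    pb_out <- matrix(0, 40, 2)
    for (i in 1:40) {
      repeat {
        cand <- c(runif(1, 0, 512), runif(1, 0, 512))
        pred <- tr[, 1:2] %*% pa_out[i, ] + tr[, 3]
        if (sqrt(sum((cand - pred)^2)) > 8) break
      }
      pb_out[i, ] <- cand
    }
    list(pa = rbind(pa_in, pa_out), pb = rbind(pb_in, pb_out), tr = tr)
  }
  d <- mk(31)
  fit <- estimate_transform_ransac(d$pa, d$pb, n_iterations = 10000, seed = 2)
  expect_true(all(!fit$inliers[61:100]))
  expect_true(all(fit$inliers[1:60]))
  expect_lt(corner_error(fit$transform, as_affine_transform(d$tr),
                         c(512, 512)), 0.5)
  expect_equal(fit$inlier_ratio, fit$n_inliers / fit$n_matched)
})
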