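#' Nearest-neighbour distance-ratio matching
#'
#' For every descriptor of `a`, its two nearest descriptors of `b` are found
#' under the set's metric (Euclidean for float descriptors, Hamming for
#' binary).  The putative match is kept iff `d1 / d2 < ratio_threshold`.
#' Matching is one-way (a to b).
#'
#' @param a,b `fov_features` objects (or bare descriptor matrices of a
#'   common type)
#' @param ratio_threshold distance-ratio cutoff, default 0.75
#' @return a `match_set`: data.frame with columns `idx_a`, `idx_b`
#'   (1-based row indices), `distance` (`d1`) and `ratio` (`d1/d2`), with
#'   the metric as an attribute
#' @export
match_nndr <- function(a, b, ratio_threshold = 0.75) {
  get_desc <- function(x) {
    if (inherits(x, "fov_features")) list(d = x$descriptors, m = x$metric)
    else if (is.raw(x)) list(d = x, m = "hamming")
    else list(d = x, m = "euclidean")
  }
  da <- get_desc(a); db <- get_desc(b)
  if (!identical(da$m, db$m)) {
    stop("descriptor metrics differ: ", da$m, " vs ", db$m)
  }
  if (ncol(da$d) != ncol(db$d)) {
    stop("descriptor widths differ: ", ncol(da$d), " vs ", ncol(db$d))
  }
  if (nrow(db$d) < 2) {
    stop("need at least 2 descriptors on the b side to form a distance ratio")
  }
  if (nrow(da$d) == 0) {
    out <- data.frame(idx_a = integer(0), idx_b = integer(0),
                      distance = numeric(0), ratio = numeric(0))
    attr(out, "metric") <- da$m
    class(out) <- c("match_set", "data.frame")
    return(out)
  }
  nn <- if (da$m == "hamming") cpp_nndr_hamming(da$d, db$d) else cpp_nndr_l2(da$d, db$d)
  ratio <- ifelse(nn[, 4] > 0, nn[, 3] / nn[, 4], ifelse(nn[, 3] > 0, 1, 0))
  keep <- ratio < ratio_threshold
  out <- data.frame(idx_a = which(keep), idx_b = as.integer(nn[keep, 1]),
                    distance = nn[keep, 3], ratio = ratio[keep])
  rownames(out) <- NULL
  attr(out, "metric") <- da$m
  class(out) <- c("match_set", "data.frame")
  out
}

#' Robust affine estimation from matched points (RANSAC)
#'
#' Fits the 6-parameter affine model from minimal samples of 3 matches,
#' keeps the largest consensus set (reprojection error at most
#' `reproj_threshold` pixels), refits by least squares on the inliers, and
#' permits early exit once the confidence bound on having drawn an
#' outlier-free sample is met.
#'
#' @param pts_a,pts_b n x 2 matrices of matched (x, y) coordinates; the
#'   model maps `pts_a` onto `pts_b`
#' @param n_iterations maximum iterations (default 150000)
#' @param confidence early-exit confidence (default 0.999)
#' @param reproj_threshold inlier reprojection threshold in pixels
#' @param seed integer seed for the sampler
#' @return list with `transform` (`affine_transform`), `inliers` (logical),
#'   `n_inliers`, `n_matched`, `inlier_ratio` and `n_iter`
#' @export
estimate_transform_ransac <- function(pts_a, pts_b, n_iterations = 150000,
                                      confidence = 0.999,
                                      reproj_threshold = 3, seed = 1) {
  pts_a <- matrix(as.numeric(as.matrix(pts_a)), ncol = 2)
  pts_b <- matrix(as.numeric(as.matrix(pts_b)), ncol = 2)
  n <- nrow(pts_a)
  stopifnot(nrow(pts_b) == n)
  if (n < 3) {
    stop("RANSAC needs at least 3 matches, got ", n)
  }
  r <- cpp_ransac_affine(pts_a, pts_b, as.integer(n_iterations), confidence,
                         reproj_threshold, as.numeric(seed))
  if (!isTRUE(r$ok)) {
    stop("RANSAC failed: no non-degenerate minimal sample found among ",
         n, " matches (collinear or coincident points)")
  }
  list(transform = as_affine_transform(r$transform),
       inliers = as.logical(r$inliers),
       n_inliers = r$n_inliers,
       n_matched = n,
       inlier_ratio = r$n_inliers / n,
       n_iter = r$n_iter)
}
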