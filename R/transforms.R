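#' Planar affine transforms
#'
#' An `affine_transform` is a 2x3 matrix `[a b e; c d f]` mapping a point
#' `(x, y)` to `(a x + b y + e, c x + d y + f)`.  Coordinates are zero-based
#' with `x` along columns, `y` along rows, and the origin at the centre of
#' the top-left pixel.
#'
#' @param a,b,c,d unitless linear part
#' @param e,f translation in pixels
#' @return an `affine_transform` object
#' @export
#' @examples
#' t1 <- affine_transform(e = 10, f = -5)
#' transform_points(t1, cbind(0, 0))
affine_transform <- function(a = 1, b = 0, c = 0, d = 1, e = 0, f = 0) {
  m <- matrix(as.numeric(c(a, c, b, d, e, f)), 2, 3)
  stopifnot(all(is.finite(m)))
  structure(m, class = "affine_transform")
}

#' Coerce a 2x3 or 3x3 matrix to an affine transform
#' @param m numeric matrix, 2x3 (or 3x3 with last row 0 0 1)
#' @return an `affine_transform`
#' @export
as_affine_transform <- function(m) {
  if (inherits(m, "affine_transform")) return(m)
  m <- as.matrix(m)
  if (all(dim(m) == c(3, 3))) m <- m[1:2, , drop = FALSE]
  stopifnot(all(dim(m) == c(2, 3)), all(is.finite(m)))
  structure(matrix(as.numeric(m), 2, 3), class = "affine_transform")
}

#' @export
print.affine_transform <- function(x, ...) {
  cat("<affine_transform>\n")
  m <- unclass(x)
  dimnames(m) <- list(c("x'", "y'"), c("x", "y", "1"))
  print(round(m, 6))
  invisible(x)
}

linear_part <- function(t) unclass(t)[, 1:2, drop = FALSE]

#' Determinant of the linear part of a transform
#' @param t an `affine_transform`
#' @return scalar determinant
#' @export
transform_det <- function(t) {
  m <- linear_part(as_affine_transform(t))
  m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1]
}

#' Invert an affine transform
#' @param t an `affine_transform`
#' @return the inverse `affine_transform`
#' @export
invert_transform <- function(t) {
  t <- as_affine_transform(t)
  d <- transform_det(t)
  if (abs(d) < 1e-12) {
    stop("transform is not invertible (determinant ", format(d), ")")
  }
  m <- unclass(t)
  li <- matrix(c(m[2, 2], -m[2, 1], -m[1, 2], m[1, 1]), 2, 2) / d
  structure(cbind(li, -li %*% m[, 3]), class = "affine_transform")
}

#' Compose two affine transforms
#'
#' Returns the transform applying `t2` first, then `t1` (matrix order).
#' @param t1,t2 `affine_transform` objects
#' @return the composed `affine_transform`
#' @export
compose_transforms <- function(t1, t2) {
  t1 <- unclass(as_affine_transform(t1))
  t2 <- unclass(as_affine_transform(t2))
  l <- t1[, 1:2] %*% t2[, 1:2]
  structure(cbind(l, t1[, 1:2] %*% t2[, 3] + t1[, 3]), class = "affine_transform")
}

#' Apply a transform to points
#' @param t an `affine_transform`
#' @param xy n x 2 matrix of (x, y) coordinates
#' @return n x 2 matrix of mapped coordinates
#' @export
transform_points <- function(t, xy) {
  m <- unclass(as_affine_transform(t))
  xy <- matrix(as.numeric(as.matrix(xy)), ncol = 2)
  sweep(xy %*% t(m[, 1:2]), 2, m[, 3], "+")
}

#' Mean displacement of the frame corners between two transforms
#'
#' The standard registration-accuracy summary: the four corners of a
#' `shape[1]` x `shape[2]` frame are mapped by both transforms and the mean
#' Euclidean displacement is returned (pixels).
#'
#' @param t_est,t_true `affine_transform` objects
#' @param shape frame dimensions `c(height, width)` in pixels
#' @return mean corner displacement in pixels
#' @export
corner_error <- function(t_est, t_true, shape) {
  h <- shape[1]; w <- shape[2]
  corners <- cbind(c(0, w - 1, 0, w - 1), c(0, 0, h - 1, h - 1))
  pe <- transform_points(t_est, corners)
  pt <- transform_points(t_true, corners)
  mean(sqrt(rowSums((pe - pt)^2)))
}
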