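#' Camera pose parameterization of a positive-determinant affine map
#'
#' Any 2x2 linear map `A` with positive determinant decomposes as
#' `A = lambda * R(psi) %*% diag(t, 1) %*% R(phi)`, where `lambda > 0` is the
#' camera zoom, `psi` the camera spin about the optical axis, `t >= 1` the
#' tilt (axis compression factor induced by a latitude change, `t = 1/cos
#' theta`), and `phi` the longitude of the optical axis.  `theta =
#' arccos(1/t)` is carried along as a derived field.
#'
#' `phi` is canonical in `[0, pi)` and `psi` in `[0, 2*pi)`; the pair
#' `(psi, phi)` is unique up to the joint flip `(psi + pi, phi + pi)`, which
#' the canonical `phi` range removes.  For `t == 1` the longitude is
#' degenerate and is stored as 0.
#'
#' @param lambda_zoom positive zoom factor
#' @param psi camera spin, radians
#' @param tilt tilt `t >= 1`
#' @param phi longitude, radians
#' @return an `affine_pose` object (list with fields `lambda_zoom`, `psi`,
#'   `tilt`, `phi`, `theta`)
#' @export
#' @examples
#' p <- affine_pose(tilt = 2, phi = pi / 4)
#' compose_affine(p)
affine_pose <- function(lambda_zoom = 1, psi = 0, tilt = 1, phi = 0) {
  stopifnot(is.numeric(lambda_zoom), lambda_zoom > 0,
            is.numeric(tilt), tilt >= 1,
            is.finite(psi), is.finite(phi))
  psi <- psi %% (2 * pi)
  phi <- phi %% pi
  if (abs(tilt - 1) < 1e-12) {
    tilt <- 1
    phi <- 0
  }
  structure(list(lambda_zoom = lambda_zoom, psi = psi, tilt = tilt,
                 phi = phi, theta = acos(1 / tilt)),
            class = "affine_pose")
}

#' @export
print.affine_pose <- function(x, ...) {
  cat(sprintf(
    "<affine_pose> zoom=%.4g spin=%.2f deg tilt=%.4g (latitude %.1f deg) longitude=%.1f deg\n",
    x$lambda_zoom, x$psi * 180 / pi, x$tilt, x$theta * 180 / pi, x$phi * 180 / pi))
  invisible(x)
}

rot2 <- function(a) matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)

#' Compose a camera pose into an affine transform
#'
#' Builds the linear map `lambda * R(psi) %*% diag(t, 1) %*% R(phi)` with
#' zero translation.  Its determinant is `lambda^2 * t > 0`.
#'
#' @param pose an `affine_pose`
#' @return an `affine_transform` with `e = f = 0`
#' @export
compose_affine <- function(pose) {
  stopifnot(inherits(pose, "affine_pose"))
  l <- pose$lambda_zoom *
    rot2(pose$psi) %*% diag(c(pose$tilt, 1)) %*% rot2(pose$phi)
  structure(cbind(l, c(0, 0)), class = "affine_transform")
}

#' Decompose an affine transform into a camera pose
#'
#' The linear part is factored by singular value decomposition:
#' `lambda` is the smaller singular value, the tilt is the ratio of the two
#' singular values, and the rotation factors give spin and longitude.  The
#' translation part is ignored.  Only positive-determinant maps admit this
#' decomposition; others are rejected.
#'
#' @param m an `affine_transform` (or 2x3/3x3/2x2 matrix)
#' @return an `affine_pose`; `compose_affine(decompose_affine(m))`
#'   reproduces the linear part of `m` to numerical precision
#' @export
decompose_affine <- function(m) {
  if (is.matrix(m) && all(dim(m) == c(2, 2))) m <- cbind(m, c(0, 0))
  m <- as_affine_transform(m)
  d <- transform_det(m)
  if (d <= 0) {
    stop("only transforms with positive determinant decompose as a camera pose; ",
         "determinant is ", format(d))
  }
  l <- linear_part(m)
  s <- svd(l)
  # force both factors to be proper rotations (det +1); the determinant of
  # the input being positive makes det(u) and det(v) share a sign
  if (det(s$u) < 0) {
    s$u[, 2] <- -s$u[, 2]
    s$v[, 2] <- -s$v[, 2]
  }
  psi <- atan2(s$u[2, 1], s$u[1, 1])
  phi <- atan2(s$v[1, 2], s$v[1, 1])  # angle of t(v) = R(phi)
  lambda <- s$d[2]
  tilt <- s$d[1] / s$d[2]
  if (abs(tilt - 1) < 1e-9) {
    # longitude is degenerate: fold everything into the spin
    return(affine_pose(lambda_zoom = lambda, psi = (psi + phi) %% (2 * pi),
                       tilt = 1, phi = 0))
  }
  # canonicalize phi into [0, pi) through the joint flip
  if (phi < 0) {
    phi <- phi + pi
    psi <- psi + pi
  }
  affine_pose(lambda_zoom = lambda, psi = psi %% (2 * pi), tilt = tilt,
              phi = phi)
}

#' Tilt/longitude sampling grid for affine view simulation
#'
#' Tilts follow the geometric series `t_k = sqrt(2)^k`, `k = 0 ..
#' max_tilt_index`.  For `t = 1` the single frontal pose is used; for each
#' `t > 1` the longitudes are `phi = m * delta`, `m = 0, 1, ...` with
#' `delta = 72 / t` degrees and `m * delta < 180`.  Ordering is
#' deterministic: increasing tilt, then increasing longitude.
#'
#' @param max_tilt_index integer in 0..8; the default 5 reaches tilt
#'   `4 * sqrt(2)` (latitude about 79.8 degrees)
#' @return data.frame with columns `tilt` and `phi` (radians)
#' @export
#' @examples
#' nrow(sample_pose_grid(5))
sample_pose_grid <- function(max_tilt_index = 5) {
  stopifnot(length(max_tilt_index) == 1, max_tilt_index >= 0,
            max_tilt_index <= 8, max_tilt_index == round(max_tilt_index))
  rows <- list(data.frame(tilt = 1, phi = 0))
  for (k in seq_len(max_tilt_index)) {
    t_k <- 2^(k / 2)                       # even k are exact powers of two
    delta <- 72 / t_k                      # degrees
    # strict m * delta < 180 on exact reals; 1e-9 deg guards the boundary
    # cases (t = 2, 4) against one-ulp rounding
    m <- 0:floor((180 - 1e-9) / delta)
    phi_deg <- m * delta
    phi_deg <- phi_deg[phi_deg < 180 - 1e-9]
    rows[[k + 1]] <- data.frame(tilt = t_k, phi = phi_deg * pi / 180)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
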