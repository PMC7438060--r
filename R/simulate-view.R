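#' Simulate the view of an image under a camera tilt
#'
#' The image is rotated by the longitude `phi` (bounding-box expansion,
#' bilinear interpolation, background 0), blurred along the to-be-compressed
#' axis with a Gaussian of `sigma = 0.8 * sqrt(tilt^2 - 1)` to prevent
#' aliasing, and subsampled by the tilt factor along that axis (the x axis
#' of the rotated frame).  `to_view` and `from_view` record the exact pixel
#' mapping, including the rotation's bounding-box translation, and are exact
#' inverses.
#'
#' @param image 2-D numeric matrix (grayscale, any range)
#' @param tilt tilt `t >= 1`
#' @param phi longitude in radians
#' @return a `simulated_view`: list with `image`, `pose` (`affine_pose`),
#'   `to_view` and `from_view` (`affine_transform`s, original <-> view) and
#'   `antialias_sigma`
#' @export
simulate_view <- function(image, tilt, phi = 0) {
  stopifnot(is.matrix(image), nrow(image) > 0, ncol(image) > 0, tilt >= 1)
  pose <- affine_pose(tilt = tilt, phi = phi)
  h <- nrow(image); w <- ncol(image)
  if (pose$tilt == 1 && pose$phi == 0) {
    idt <- affine_transform()
    return(structure(list(image = image, pose = pose, to_view = idt,
                          from_view = idt, antialias_sigma = 0),
                     class = "simulated_view"))
  }
  phi <- pose$phi
  # rotation with bounding-box translation
  r <- rot2(phi)
  corners <- cbind(c(0, w - 1, 0, w - 1), c(0, 0, h - 1, h - 1))
  rc <- corners %*% t(r)
  off <- apply(rc, 2, min)
  rot_t <- structure(cbind(r, -off), class = "affine_transform")
  rw <- ceiling(max(rc[, 1]) - off[1]) + 1
  rh <- ceiling(max(rc[, 2]) - off[2]) + 1
  img_rot <- if (phi == 0) image else {
    cpp_warp_affine(image, unclass(invert_transform(rot_t)), rh, rw, 1L, 0)
  }
  # anti-alias blur along the compressed (x) axis, then subsample by t
  sigma <- if (tilt > 1) 0.8 * sqrt(tilt^2 - 1) else 0
  if (sigma > 0) img_rot <- cpp_gauss_blur(img_rot, sigma, 0)
  tilt_t <- affine_transform(a = 1 / tilt)
  to_view <- compose_transforms(tilt_t, rot_t)
  vw <- max(1L, ceiling(ncol(img_rot) / tilt))
  vh <- nrow(img_rot)
  if (vw < 8 || vh < 8) {
    stop("simulated view degenerates to ", vh, " x ", vw,
         " pixels; refuse to detect features on it")
  }
  from_view <- invert_transform(to_view)
  # sample the rotated image at x_rot = t * x_view
  sub <- affine_transform(a = tilt)
  view <- cpp_warp_affine(img_rot, unclass(sub), vh, vw, 1L, 0)
  structure(list(image = view, pose = pose, to_view = to_view,
                 from_view = from_view, antialias_sigma = sigma),
            class = "simulated_view")
}

#' Map keypoints detected in a simulated view back to the original frame
#'
#' Locations are mapped through `from_view`; keypoints landing outside the
#' original image bounds are dropped (with their descriptors).  Descriptor
#' payloads are untouched.
#'
#' @param features a detection result from [detect_and_describe()] whose
#'   coordinates live in the view frame
#' @param view a `simulated_view`
#' @param original_shape `c(height, width)` of the original image
#' @return the detection result with keypoints in original-frame coordinates
#' @export
backproject_keypoints <- function(features, view, original_shape) {
  stopifnot(inherits(view, "simulated_view"))
  kp <- features$keypoints
  if (nrow(kp) == 0) return(features)
  xy <- transform_points(view$from_view, kp[, c("x", "y")])
  keep <- xy[, 1] >= 0 & xy[, 1] <= original_shape[2] - 1 &
    xy[, 2] >= 0 & xy[, 2] <= original_shape[1] - 1
  kp$x <- xy[, 1]
  kp$y <- xy[, 2]
  features$keypoints <- kp[keep, , drop = FALSE]
  features$descriptors <- features$descriptors[keep, , drop = FALSE]
  features
}

#' Pool affine-simulated features across the tilt/longitude grid
#'
#' Runs [simulate_view()] for every pose of [sample_pose_grid()], detects and
#' describes keypoints on each simulated image, backprojects them to the
#' original frame, pools them, and suppresses duplicates (keypoints closer
#' than 1 px with identical descriptors collapse to the first).
#'
#' @param image 2-D numeric matrix, 0..255
#' @param backend backend name, see [detect_and_describe()]
#' @param max_tilt_index tilt grid extent, see [sample_pose_grid()]
#' @param dedupe_tol descriptor-agreement tolerance for duplicate collapse:
#'   Euclidean distance for float descriptors, fraction of differing bits
#'   for binary ones.  0 demands identical descriptors; the small default
#'   also catches the near-duplicates that overlapping views produce
#'   through resampling
#' @param ... further arguments to [detect_and_describe()]
#' @return a detection result (keypoints data.frame with a
#'   `source_pose_index` column, descriptors, metric, backend)
#' @export
detect_features_affine <- function(image, backend, max_tilt_index = 5,
                                   dedupe_tol = 0.02, ...) {
  grid <- sample_pose_grid(max_tilt_index)
  shape <- dim(image)
  kps <- list(); descs <- list(); metric <- NULL
  for (i in seq_len(nrow(grid))) {
    view <- simulate_view(image, grid$tilt[i], grid$phi[i])
    det <- detect_and_describe(view$image, backend, ...)
    metric <- det$metric
    det <- backproject_keypoints(det, view, shape)
    if (nrow(det$keypoints) == 0) next
    det$keypoints$source_pose_index <- i
    kps[[length(kps) + 1]] <- det$keypoints
    descs[[length(descs) + 1]] <- det$descriptors
  }
  if (length(kps) == 0) {
    empty <- detect_and_describe(matrix(0, 32, 32), backend, ...)
    empty$keypoints$source_pose_index <- integer(0)
    return(empty)
  }
  kp <- do.call(rbind, kps)
  desc <- do.call(rbind, descs)
  xy <- as.matrix(kp[, c("x", "y")])
  keep <- if (identical(metric, "hamming")) {
    cpp_dedupe_hamming(xy, desc, as.integer(round(dedupe_tol * 8 * ncol(desc))))
  } else {
    # float descriptors are unit-normalized; reuse the fractional tolerance
    # as an absolute Euclidean radius (2.5x to span the unit sphere scale)
    cpp_dedupe_l2(xy, desc, 2.5 * dedupe_tol)
  }
  structure(list(keypoints = kp[keep, , drop = FALSE],
                 descriptors = desc[keep, , drop = FALSE],
                 metric = metric, backend = backend),
            class = "fov_features")
}
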