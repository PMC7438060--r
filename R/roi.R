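#' Build a filtered binary ROI mask from a label or binary image
#'
#' Connected components (8-connectivity) with fewer than `min_pixels` pixels
#' are dropped — the size filter that removes dendritic spines misdetected
#' as neurons.  Surviving ROIs are painted 255 on a 0 background.  A mask
#' whose values are only \{0, 1\} or \{0, 255\} is relabelled by connected
#' components; any other nonnegative integer image is taken as label ids
#' directly.
#'
#' @param label_mask matrix of nonnegative integer labels (0 = background)
#'   or a binary image
#' @param min_pixels minimum ROI area in pixels; an ROI of exactly
#'   `min_pixels` is kept (default 60)
#' @return an `roi_mask`: list with `image` (0/255 matrix), `rois` (list of
#'   n x 2 zero-based (x, y) pixel coordinate matrices) and `centroids`
#'   (n_roi x 2 matrix of (x, y))
#' @export
binarize_and_filter <- function(label_mask, min_pixels = 60) {
  stopifnot(is.matrix(label_mask), all(label_mask >= 0))
  vals <- unique(as.vector(label_mask))
  binary <- all(vals %in% c(0, 1)) || all(vals %in% c(0, 255))
  lab <- if (binary) {
    cpp_label8(matrix(as.integer(label_mask != 0), nrow(label_mask)))
  } else {
    matrix(as.integer(round(label_mask)), nrow(label_mask))
  }
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  img <- matrix(0, nrow(label_mask), ncol(label_mask))
  rois <- list()
  centroids <- NULL
  for (id in ids) {
    px <- which(lab == id, arr.ind = TRUE)  # (row, col), 1-based
    if (nrow(px) < min_pixels) next
    xy <- cbind(x = px[, 2] - 1, y = px[, 1] - 1)
    img[px] <- 255
    rois[[length(rois) + 1]] <- xy
    centroids <- rbind(centroids, colMeans(xy))
  }
  if (is.null(centroids)) centroids <- matrix(numeric(0), 0, 2)
  colnames(centroids) <- c("x", "y")
  structure(list(image = img, rois = rois, centroids = centroids),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %d x %d, %d ROIs (%d foreground px)\n",
              nrow(x$image), ncol(x$image), length(x$rois),
              sum(x$image > 0)))
  invisible(x)
}

as_mask_image <- function(m) {
  if (inherits(m, "roi_mask")) m$image else m
}

#' Pearson correlation between two ROI masks
#'
#' The two masks are flattened to 1-D vectors and the Pearson linear
#' correlation coefficient is computed.  Because Pearson correlation is
#' invariant to affine rescaling, 0/255 and 0/1 encodings give identical
#' values.  A constant mask (no neurons, or all neurons) has zero variance
#' and no defined correlation: this is an error, not 0.
#'
#' @param mask_a,mask_b `roi_mask` objects or 0/255 matrices of equal shape
#' @return Pearson r in `[-1, 1]`
#' @export
mask_correlation <- function(mask_a, mask_b) {
  a <- as_mask_image(mask_a)
  b <- as_mask_image(mask_b)
  stopifnot(all(dim(a) == dim(b)))
  if (sd(a) == 0 || sd(b) == 0) {
    stop("mask correlation is undefined for a constant mask (zero variance)")
  }
  cor(as.vector(a), as.vector(b))
}

#' Fourier-spectrum sharpness of an FOV image
#'
#' Sharpness is the fraction of pixels in the image's centred Fourier
#' spectrum whose magnitude exceeds `M / 1000`, where `M` is the maximum
#' magnitude of the template's centred spectrum.  Lower values mean a more
#' blurred image.
#'
#' @param image 2-D matrix to score
#' @param template 2-D matrix of the template session (same shape);
#'   defaults to the image itself
#' @return a `sharpness_report`: list with `value` in (0, 1], `threshold`
#'   and `template_max_M`
#' @export
sharpness <- function(image, template = image) {
  stopifnot(all(dim(image) == dim(template)))
  mag_t <- Mod(fft(template))
  m <- max(mag_t)
  thr <- m / 1000
  mag_i <- Mod(fft(image))
  structure(list(value = sum(mag_i > thr) / length(mag_i),
                 threshold = thr, template_max_M = m),
            class = "sharpness_report")
}

#' @export
print.sharpness_report <- function(x, ...) {
  cat(sprintf("<sharpness> %.4f (threshold M/1000 = %.4g)\n",
              x$value, x$threshold))
  invisible(x)
}

#' Count neurons common to two ROI masks
#'
#' A transform carrying mask A's frame onto mask B's frame (the ground
#' truth of a synthetic pair, or an estimated registration) maps A's ROI
#' centroids; an ROI pair is a common neuron when the transformed centroid
#' of an A ROI lies within `centroid_radius` pixels of a B ROI centroid.
#' Pairing is greedy nearest-first and one-to-one.  This operationalizes
#' what is otherwise a manual curation step; the radius is a package
#' definition, not a measured quantity.
#'
#' @param mask_a,mask_b `roi_mask` objects
#' @param transform `affine_transform` from A's frame to B's frame
#'   (default identity)
#' @param centroid_radius pairing radius in pixels (default 5)
#' @return list with `count` and `pairs` (m x 2 matrix of ROI indices in A
#'   and B)
#' @export
count_common_neurons <- function(mask_a, mask_b,
                                 transform = affine_transform(),
                                 centroid_radius = 5) {
  stopifnot(inherits(mask_a, "roi_mask"), inherits(mask_b, "roi_mask"))
  transform <- as_affine_transform(transform)
  invert_transform(transform)  # reject non-invertible transforms
  na <- nrow(mask_a$centroids)
  nb <- nrow(mask_b$centroids)
  if (na == 0 || nb == 0) {
    return(list(count = 0L, pairs = matrix(integer(0), 0, 2,
                                           dimnames = list(NULL, c("a", "b")))))
  }
  ca <- transform_points(transform, mask_a$centroids)
  d <- sqrt(outer(ca[, 1], mask_b$centroids[, 1], "-")^2 +
              outer(ca[, 2], mask_b$centroids[, 2], "-")^2)
  pairs <- NULL
  repeat {
    m <- which.min(d)
    if (!length(m) || d[m] > centroid_radius) break
    i <- (m - 1) %% na + 1
    j <- (m - 1) %/% na + 1
    pairs <- rbind(pairs, c(i, j))
    d[i, ] <- Inf
    d[, j] <- Inf
  }
  if (is.null(pairs)) pairs <- matrix(integer(0), 0, 2)
  colnames(pairs) <- c("a", "b")
  list(count = nrow(pairs), pairs = pairs)
}
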