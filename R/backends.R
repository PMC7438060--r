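#' Detect and describe keypoints with one of five backends
#'
#' The backends are native implementations in the style of the five
#' classical feature families.  Float-descriptor backends are matched under
#' the Euclidean metric, binary backends under Hamming distance:
#'
#' * `SIFT` — difference-of-Gaussian extrema, 128-d gradient-orientation
#'   histogram descriptor (Euclidean).
#' * `SURF` — Hessian-determinant extrema on a Gaussian scale space, 64-d
#'   block descriptor of signed/absolute gradient sums (Euclidean).
#' * `AKAZE` — Hessian-determinant extrema with a 486-bit binary grid
#'   comparison descriptor over per-cell gradient statistics (Hamming).
#' * `BRISK` — multiscale FAST corners, 512-bit concentric-ring sampling
#'   pattern (Hamming).
#' * `ORB` — multiscale FAST corners ranked by response with a fixed
#'   feature budget, 256-bit steered random point-pair tests (Hamming).
#'
#' Output is deterministic for a fixed input and configuration.
#'
#' @param image 2-D numeric matrix on the 0..255 scale
#' @param backend one of `"SIFT"`, `"SURF"`, `"AKAZE"`, `"BRISK"`, `"ORB"`
#' @param contrast_thresh DoG contrast threshold (SIFT), on unit-scaled
#'   intensities; the default follows the family's published convention of
#'   0.04 divided by the scales-per-octave
#' @param edge_ratio DoG edge rejection ratio (SIFT)
#' @param hessian_thresh Hessian-determinant response threshold
#'   (SURF/AKAZE), on unit-scaled intensities
#' @param fast_thresh FAST corner threshold in gray levels (BRISK/ORB)
#' @param n_features ORB feature budget (the other backends are uncapped up
#'   to `max_keypoints`)
#' @param max_keypoints safety cap per call
#' @return an object of class `fov_features`: list with `keypoints`
#'   (data.frame `x`, `y`, `scale`, `orientation`, `response`; zero-based
#'   pixel coordinates), `descriptors` (numeric matrix or raw byte matrix,
#'   one row per keypoint), `metric` (`"euclidean"` or `"hamming"`) and
#'   `backend`
#' @export
#' @examples
#' img <- matrix(0, 64, 64)
#' img[20:26, 30:36] <- 200
#' det <- detect_and_describe(img, "ORB")
#' nrow(det$keypoints)
detect_and_describe <- function(image, backend,
                                contrast_thresh = 0.04 / 3, edge_ratio = 10,
                                hessian_thresh = 1e-4, fast_thresh = 10,
                                n_features = 500, max_keypoints = 5000) {
  stopifnot(is.matrix(image), is.numeric(image))
  backend <- toupper(backend)
  backends <- c("SIFT", "SURF", "AKAZE", "BRISK", "ORB")
  if (!backend %in% backends) {
    stop("unknown backend '", backend, "'; available: ",
         paste(backends, collapse = ", "))
  }
  if (min(dim(image)) < 32) {
    stop("image of ", nrow(image), " x ", ncol(image),
         " is too small for the ", backend, " scale pyramid")
  }
  res <- switch(backend,
    SIFT = cpp_sift(image, contrast_thresh, edge_ratio, as.integer(max_keypoints)),
    SURF = cpp_surf(image, hessian_thresh, as.integer(max_keypoints)),
    AKAZE = cpp_akaze(image, hessian_thresh, as.integer(max_keypoints)),
    BRISK = cpp_brisk(image, fast_thresh, as.integer(max_keypoints)),
    ORB = cpp_orb(image, as.integer(n_features), fast_thresh))
  kp <- as.data.frame(res$keypoints)
  structure(list(keypoints = kp, descriptors = res$descriptors,
                 metric = if (backend %in% c("SIFT", "SURF")) "euclidean" else "hamming",
                 backend = backend),
            class = "fov_features")
}

#' @export
print.fov_features <- function(x, ...) {
  cat(sprintf("<fov_features> backend=%s metric=%s keypoints=%d descriptor_width=%d\n",
              x$backend, x$metric, nrow(x$keypoints), ncol(x$descriptors)))
  invisible(x)
}
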