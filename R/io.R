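#' Read a field-of-view image
#'
#' Accepts single-plane or stack TIFF and PNG.  A stack is mean-projected;
#' the result is min-max normalized to the 8-bit 0..255 scale.  RGB input is
#' refused unless `gray = TRUE`, in which case the channel mean is taken
#' before normalization.
#'
#' @param path file path (.tif/.tiff/.png)
#' @param gray convert RGB to grayscale by channel mean
#' @return numeric matrix 0..255 with attributes `source_bit_depth` and
#'   `projection` (`"none"` or `"mean"`)
#' @export
read_fov_image <- function(path, gray = FALSE) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    tif = , tiff = tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE),
                            error = function(e) {
                              stop("cannot read '", path, "' as TIFF: ",
                                   conditionMessage(e))
                            }),
    png = tryCatch(list(png::readPNG(path, info = TRUE)),
                   error = function(e) {
                     stop("cannot read '", path, "' as PNG: ",
                          conditionMessage(e))
                   }),
    stop("unsupported image format '", ext, "' (use TIFF or PNG)"))
  flatten <- function(plane) {
    if (length(dim(plane)) == 3) {
      if (!gray) {
        stop("'", path, "' has ", dim(plane)[3],
             " channels; pass gray = TRUE to average them")
      }
      plane <- apply(plane[, , seq_len(min(3, dim(plane)[3])), drop = FALSE],
                     c(1, 2), mean)
    }
    plane
  }
  planes <- lapply(raw, flatten)
  projection <- if (length(planes) > 1) "mean" else "none"
  img <- Reduce(`+`, planes) / length(planes)
  info <- attr(raw[[1]], "info")
  bit_depth <- if (!is.null(info$bits.per.sample)) info$bits.per.sample else 8L
  rng <- range(img)
  img <- if (rng[2] > rng[1]) (img - rng[1]) / (rng[2] - rng[1]) * 255 else img * 0
  attr(img, "source_bit_depth") <- bit_depth
  attr(img, "projection") <- projection
  img
}

#' Read an ROI mask image and filter it
#'
#' @param path PNG or TIFF, binary (0/255) or labelled
#' @param min_pixels ROI size filter, see [binarize_and_filter()]
#' @return an `roi_mask`
#' @export
read_mask <- function(path, min_pixels = 60) {
  ext <- tolower(tools::file_ext(path))
  m <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported mask format '", ext, "'"))
  if (length(dim(m)) == 3) m <- m[, , 1]
  binarize_and_filter(round(m * 255), min_pixels)
}

#' Write a 0/255 mask as PNG
#' @param mask `roi_mask` or 0/255 matrix
#' @param path output path (.png)
#' @export
write_mask <- function(mask, path) {
  m <- as_mask_image(mask)
  png::writePNG(m / 255, path)
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects every tunable of the alignment pipeline with the defaults used
#' throughout: NNDR ratio 0.75, RANSAC 150000 iterations at 99.9 percent
#' confidence, 3 px reprojection threshold, 100 repeats, CLAHE tiles 8x8
#' with clip limit 1 (off by default for the affine pipeline), minimum ROI
#' size 60 px.
#'
#' @param backend_name backend, see [detect_and_describe()]
#' @param max_tilt_index pose grid extent
#' @param nndr_ratio NNDR threshold
#' @param ransac_iterations,ransac_confidence,reproj_threshold_px RANSAC
#' @param n_repeats repeated estimation count
#' @param clahe,clahe_tile,clahe_clip CLAHE preprocessing settings
#' @param min_roi_pixels ROI size filter
#' @param seed base seed
#' @return a `run_config` list
#' @export
run_config <- function(backend_name = "SIFT", max_tilt_index = 5,
                       nndr_ratio = 0.75, ransac_iterations = 150000,
                       ransac_confidence = 0.999, reproj_threshold_px = 3,
                       n_repeats = 100, clahe = FALSE, clahe_tile = c(8, 8),
                       clahe_clip = 1, min_roi_pixels = 60, seed = 1) {
  structure(list(backend_name = backend_name,
                 max_tilt_index = max_tilt_index,
                 nndr_ratio = nndr_ratio,
                 ransac_iterations = ransac_iterations,
                 ransac_confidence = ransac_confidence,
                 reproj_threshold_px = reproj_threshold_px,
                 n_repeats = n_repeats, clahe = clahe,
                 clahe_tile = clahe_tile, clahe_clip = clahe_clip,
                 min_roi_pixels = min_roi_pixels, seed = seed),
            class = "run_config")
}

#' Read/write a run configuration as YAML
#' @param config a `run_config`
#' @param path file path
#' @return `read_config` returns a `run_config`
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' Serialize an alignment result to JSON
#'
#' The transform is stored as 6 numbers `[a, b, e, c, d, f]` (row-major
#' 2x3); counts, per-repeat L1 scores and seeds are stored verbatim, so
#' `read_alignment(write_alignment(x))` reproduces the result field by
#' field.
#'
#' @param result a `fov_alignment`
#' @param path output JSON path
#' @export
write_alignment <- function(result, path) {
  stopifnot(inherits(result, "fov_alignment"))
  obj <- list(transform = as.vector(t(unclass(result$transform))),
              n_inliers = result$n_inliers,
              n_matched = result$n_matched,
              inlier_ratio = result$inlier_ratio,
              n_features_moving = result$n_features_moving,
              n_features_template = result$n_features_template,
              l1_scores = result$l1_scores,
              selected_repeat = result$selected_repeat,
              repeat_seeds = result$repeat_seeds,
              backend = result$backend,
              simulated = result$simulated,
              seed = result$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_alignment
#' @param path JSON path to read
#' @return a `fov_alignment`
#' @export
read_alignment <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  required <- c("transform", "n_inliers", "n_matched", "l1_scores",
                "selected_repeat", "backend", "seed")
  missing <- setdiff(required, names(obj))
  if (length(missing)) {
    stop("alignment file '", path, "' lacks required field(s): ",
         paste(missing, collapse = ", "))
  }
  if (length(obj$transform) != 6) {
    stop("alignment file '", path, "' has a malformed 'transform' ",
         "(expected 6 numbers, got ", length(obj$transform), ")")
  }
  structure(list(transform = as_affine_transform(
                   matrix(obj$transform, 2, 3, byrow = TRUE)),
                 n_inliers = obj$n_inliers,
                 n_matched = obj$n_matched,
                 inlier_ratio = obj$inlier_ratio,
                 n_features_moving = obj$n_features_moving,
                 n_features_template = obj$n_features_template,
                 l1_scores = obj$l1_scores,
                 selected_repeat = obj$selected_repeat,
                 repeat_seeds = obj$repeat_seeds,
                 backend = obj$backend,
                 simulated = obj$simulated,
                 seed = obj$seed),
            class = "fov_alignment")
}
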