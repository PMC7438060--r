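#' Warp an image or mask by an affine transform
#'
#' The transform maps moving-frame coordinates to template-frame
#' coordinates; the output is rendered on the template frame by inverse
#' mapping.  Masks should use nearest-neighbour interpolation so values stay
#' in \{0, 255\}; intensity images use bilinear.  Out-of-frame samples are 0.
#'
#' @param transform an `affine_transform`
#' @param image 2-D numeric matrix
#' @param interpolation `"bilinear"` or `"nearest"`
#' @param output_dim `c(height, width)` of the output frame; defaults to the
#'   input shape
#' @return warped matrix
#' @export
apply_transform <- function(transform, image,
                            interpolation = c("bilinear", "nearest"),
                            output_dim = dim(image)) {
  interpolation <- match.arg(interpolation)
  transform <- as_affine_transform(transform)
  minv <- invert_transform(transform)  # errors on non-invertible input
  cpp_warp_affine(image, unclass(minv), as.integer(output_dim[1]),
                  as.integer(output_dim[2]),
                  if (interpolation == "nearest") 0L else 1L, 0)
}

#' L1 disagreement between a warped moving mask and the template mask
#'
#' The moving ROI mask is warped by `transform` into the template frame
#' (nearest-neighbour, out-of-frame pixels 0) and the score is the sum over
#' all pixels of `|warped - template|`.  For 0/255 binary masks this equals
#' 255 times the number of pixels where exactly one mask has a neuron — the
#' symmetric difference of the two foreground supports.
#'
#' @param transform an `affine_transform` mapping moving to template frame
#' @param moving_mask,template_mask 0/255 matrices
#' @return nonnegative scalar
#' @export
l1_mask_score <- function(transform, moving_mask, template_mask) {
  transform <- as_affine_transform(transform)
  minv <- invert_transform(transform)
  cpp_l1_mask_score(moving_mask, template_mask, unclass(minv))
}

#' Contrast-limited adaptive histogram equalization
#'
#' Per-tile clipped-histogram equalization with bilinear blending between
#' neighbouring tile mappings.  The clip limit follows the convention in
#' which the per-bin ceiling is `clip_limit * tile_area / 256`: a limit of 1
#' still equalizes, it only forbids any bin from exceeding the uniform
#' share.
#'
#' @param image 2-D matrix on the 0..255 scale
#' @param tile_grid `c(nx, ny)` tiles, default 8 x 8
#' @param clip_limit contrast limiting threshold, default 1
#' @return equalized matrix, range within `[0, 255]`
#' @export
clahe_preprocess <- function(image, tile_grid = c(8, 8), clip_limit = 1) {
  stopifnot(is.matrix(image), min(image) >= 0, max(image) <= 255)
  cpp_clahe(image, as.integer(tile_grid[1]), as.integer(tile_grid[2]),
            clip_limit)
}

#' Align a moving field of view onto a template session
#'
#' The full fully affine invariant pipeline.  Both images are expanded over
#' the tilt/longitude simulation grid and features are computed once per
#' image: detect/describe per simulated view, backproject to original
#' coordinates, pool, and deduplicate.  Matching (NNDR at
#' `ratio_threshold`) and RANSAC are then run `n_repeats` times with seeds
#' `seed + i`; every candidate transform is scored by [l1_mask_score()]
#' between the warped moving raw ROI mask and the template raw mask, and the
#' arg-min transform is returned with full per-repeat provenance.  Ties keep
#' the earliest repeat.
#'
#' @param moving_image,template_image 0..255 matrices of the two sessions'
#'   mean FOV images (the template is the first recorded session)
#' @param moving_mask,template_mask raw ROI masks, 0/255, same geometry as
#'   their images
#' @param backend keypoint backend, see [detect_and_describe()]
#' @param n_repeats number of NNDR+RANSAC repeats (default 100)
#' @param seed integer; repeat i uses seed + i - 1
#' @param max_tilt_index simulation grid extent ([sample_pose_grid()]);
#'   set `simulate = FALSE` for the plain (non-simulated) backend
#' @param simulate if `FALSE`, features come from the original images only
#'   (the plain feature-based method used as a baseline)
#' @param clahe apply [clahe_preprocess()] to both images first (off by
#'   default: the fully affine pipeline does not require it)
#' @param ratio_threshold NNDR cutoff (default 0.75)
#' @param n_iterations,confidence,reproj_threshold RANSAC settings, see
#'   [estimate_transform_ransac()]
#' @param ... further detector arguments passed to [detect_and_describe()]
#' @return a `fov_alignment`: list with `transform` (moving -> template),
#'   `n_inliers`, `n_matched`, `inlier_ratio`, `n_features_moving`,
#'   `n_features_template`, `l1_scores` (one per repeat), `selected_repeat`,
#'   `repeat_seeds`, `backend`, `seed`
#' @export
align_fov <- function(moving_image, template_image, moving_mask,
                      template_mask, backend = "SIFT", n_repeats = 100,
                      seed = 1, max_tilt_index = 5, simulate = TRUE,
                      clahe = FALSE, ratio_threshold = 0.75,
                      n_iterations = 150000, confidence = 0.999,
                      reproj_threshold = 3, ...) {
  stopifnot(is.matrix(moving_image), is.matrix(template_image),
            all(dim(moving_mask) == dim(moving_image)),
            all(dim(template_mask) == dim(template_image)),
            all(moving_mask %in% c(0, 255)),
            all(template_mask %in% c(0, 255)),
            n_repeats >= 1)
  if (clahe) {
    moving_image <- clahe_preprocess(moving_image)
    template_image <- clahe_preprocess(template_image)
  }
  feat <- function(img) {
    if (simulate) detect_features_affine(img, backend, max_tilt_index, ...)
    else detect_and_describe(img, backend, ...)
  }
  fm <- feat(moving_image)
  ft <- feat(template_image)
  if (nrow(ft$keypoints) < 2 || nrow(fm$keypoints) < 3) {
    stop("not enough keypoints to align: ", nrow(fm$keypoints), " on the ",
         "moving image, ", nrow(ft$keypoints), " on the template")
  }
  matches <- match_nndr(fm, ft, ratio_threshold)
  if (nrow(matches) < 3) {
    stop("insufficient matches for RANSAC: ", nrow(matches),
         " NNDR matches (", nrow(fm$keypoints), " / ", nrow(ft$keypoints),
         " pooled features); cannot align")
  }
  pa <- as.matrix(fm$keypoints[matches$idx_a, c("x", "y")])
  pb <- as.matrix(ft$keypoints[matches$idx_b, c("x", "y")])
  repeat_seeds <- seed + seq_len(n_repeats) - 1
  l1_scores <- rep(Inf, n_repeats)
  fits <- vector("list", n_repeats)
  for (i in seq_len(n_repeats)) {
    fit <- tryCatch(
      estimate_transform_ransac(pa, pb, n_iterations, confidence,
                                reproj_threshold, seed = repeat_seeds[i]),
      error = function(e) NULL)
    if (is.null(fit) || abs(transform_det(fit$transform)) < 1e-12) next
    fits[[i]] <- fit
    l1_scores[i] <- l1_mask_score(fit$transform, moving_mask, template_mask)
  }
  if (all(is.infinite(l1_scores))) {
    stop("all ", n_repeats, " RANSAC repeats failed on ", nrow(matches),
         " matches; cannot align")
  }
  best <- which.min(l1_scores)  # earliest minimum wins
  fit <- fits[[best]]
  structure(list(transform = fit$transform,
                 n_inliers = fit$n_inliers,
                 n_matched = fit$n_matched,
                 inlier_ratio = fit$inlier_ratio,
                 n_features_moving = nrow(fm$keypoints),
                 n_features_template = nrow(ft$keypoints),
                 l1_scores = l1_scores,
                 selected_repeat = best,
                 repeat_seeds = repeat_seeds,
                 backend = backend,
                 simulated = simulate,
                 seed = seed),
            class = "fov_alignment")
}

#' @export
print.fov_alignment <- function(x, ...) {
  cat(sprintf(
    paste0("<fov_alignment> backend=%s%s features=%d/%d matched=%d ",
           "inliers=%d (ratio %.2f)\n  winning L1=%.0f at repeat %d of %d\n"),
    x$backend, if (x$simulated) " (affine-simulated)" else "",
    x$n_features_moving, x$n_features_template, x$n_matched, x$n_inliers,
    x$inlier_ratio, min(x$l1_scores), x$selected_repeat, length(x$l1_scores)))
  print(x$transform)
  invisible(x)
}
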