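#' Run alignment methods over a benchmark suite
#'
#' For every pair and backend, runs the fully affine invariant pipeline
#' (affine view simulation, pooled features, repeated NNDR+RANSAC with L1
#' mask selection) and, optionally, the plain feature-based baseline (same
#' backend, no view simulation).  Each run is scored on the pair's
#' common-neuron masks: Pearson correlation before registration, after
#' registration (moving common mask warped by the estimated transform), and
#' the mean frame-corner displacement between the estimated and true
#' transforms.  A run that fails to produce a transform (too few matches)
#' counts as unregistered: its post-alignment correlation is the
#' unregistered correlation and its corner error is that of the identity.
#'
#' @param suite result of [benchmark_suite()]
#' @param backends character vector of backend names
#' @param methods subset of `c("affine", "plain")`
#' @param n_repeats NNDR+RANSAC repeats per alignment
#' @param seed base seed for the repeat ladder
#' @param max_tilt_index simulation grid extent for the affine method (the
#'   default reaches tilt 2, ample for latitudes up to about 60 degrees)
#' @param max_keypoints per-detection feature budget keeping the suite's
#'   pooled matching tractable
#' @param ... further arguments to [align_fov()]
#' @return data.frame with one row per (pair, backend, method):
#'   `pair_id`, `stratum`, `backend`, `method`, `corr_before`,
#'   `corr_after`, `corner_error_px`, `n_inliers`, `n_matched`,
#'   `inlier_ratio`, `failed`
#' @export
evaluate_benchmark <- function(suite, backends = c("SIFT", "SURF", "AKAZE",
                                                   "BRISK", "ORB"),
                               methods = c("affine", "plain"),
                               n_repeats = 20, seed = 1, max_tilt_index = 3,
                               max_keypoints = 300, ...) {
  rows <- list()
  for (pair in suite) {
    shape <- pair$scene$frame_shape
    cm <- pair_common_masks(pair)
    corr_before <- mask_correlation(cm$moving, cm$template)
    for (backend in backends) {
      for (method in methods) {
        res <- tryCatch(
          align_fov(pair$moving$image, pair$template$image,
                    pair$moving$mask$image, pair$template$mask$image,
                    backend = backend, n_repeats = n_repeats, seed = seed,
                    max_tilt_index = max_tilt_index,
                    max_keypoints = max_keypoints,
                    simulate = (method == "affine"), ...),
          error = function(e) NULL)
        failed <- is.null(res)
        tr <- if (failed) affine_transform() else res$transform
        warped <- apply_transform(tr, cm$moving$image, "nearest",
                                  output_dim = shape)
        corr_after <- if (failed) {
          corr_before            # unregistered
        } else if (sd(warped) == 0) {
          0                      # registration emptied the frame
        } else {
          mask_correlation(warped, cm$template$image)
        }
        rows[[length(rows) + 1]] <- data.frame(
          pair_id = pair$pair_id, stratum = pair$stratum,
          backend = backend, method = method,
          corr_before = corr_before, corr_after = corr_after,
          corner_error_px = corner_error(tr, pair$true_transform, shape),
          n_inliers = if (failed) 0L else res$n_inliers,
          n_matched = if (failed) 0L else res$n_matched,
          inlier_ratio = if (failed) NA_real_ else res$inlier_ratio,
          failed = failed)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
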