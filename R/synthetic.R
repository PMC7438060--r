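with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# ellipse support radius of a Gaussian blob thresholded at amplitude / 5
blob_support_factor <- sqrt(2 * log(5))

#' Generate a ground-truth synthetic neuron scene
#'
#' Neuron centres are rejection-sampled with a minimum spacing that keeps
#' the thresholded blob supports disjoint even after moderate affine
#' stretching; blob shapes are anisotropic Gaussians sized so every
#' noiseless ROI covers at least 60 pixels at the amplitude/5 support
#' threshold (the ROI filter never silently empties a fixture).  Centres
#' stay inside the central two thirds of the frame so tilted session
#' renders keep the population in view.
#'
#' In addition to the neurons, the scene carries a fixed neuropil texture:
#' a smooth multi-scale random field, generated once on a canvas extending
#' `margin` pixels beyond the frame so that every affine session view
#' samples real scene content rather than an empty border.  Mean calcium
#' images are never blobs on a flat background — the out-of-focus neuropil
#' and vasculature give them the spatial texture that feature descriptors
#' key on — so the texture is part of the ground truth and is warped by
#' each session's transform.
#'
#' @param n_neurons number of neurons (>= 1)
#' @param frame_shape `c(height, width)` pixels
#' @param seed integer; the scene is reproducible from it
#' @param texture_base baseline neuropil intensity (gray levels)
#' @param texture_sd standard deviations of the fine and coarse texture
#'   components (gray levels)
#' @param texture_sigma correlation lengths of the two components (px)
#' @param margin texture canvas margin beyond the frame (px)
#' @return a `synthetic_scene`: list with `frame_shape`, `neuron_centers`
#'   (n x 2, zero-based (x, y)), `neuron_covariances` (list of 2x2, px^2),
#'   `neuron_amplitudes`, `texture` (canvas matrix), `margin`, `seed`
#' @export
generate_scene <- function(n_neurons, frame_shape = c(512, 512), seed = 1,
                           texture_base = 45, texture_sd = c(14, 8),
                           texture_sigma = c(2.5, 8), margin = 96) {
  stopifnot(n_neurons >= 1, length(frame_shape) == 2)
  h <- frame_shape[1]; w <- frame_shape[2]
  with_seed(seed, {
    sig_major <- runif(n_neurons, 3.1, 4.0)
    ratio <- runif(n_neurons, 1.2, 1.5)
    sig_minor <- sig_major / ratio
    ang <- runif(n_neurons, 0, pi)
    amp <- runif(n_neurons, 120, 220)
    support_r <- sig_major * blob_support_factor
    # margin: central region that survives a 1.45x stretch about the centre
    mx <- w / 2 - 0.33 * w; Mx <- w / 2 + 0.33 * w
    my <- h / 2 - 0.33 * h; My <- h / 2 + 0.33 * h
    if (Mx - mx < 24 || My - my < 24) {
      stop("frame of ", h, " x ", w, " too small for a synthetic scene")
    }
    centers <- matrix(NA_real_, n_neurons, 2)
    placed <- 0
    for (attempt in seq_len(500 * n_neurons)) {
      cand <- c(runif(1, mx, Mx), runif(1, my, My))
      ok <- TRUE
      if (placed > 0) {
        for (j in seq_len(placed)) {
          min_d <- max(12, 1.45 * (support_r[placed + 1] + support_r[j]) + 2)
          if (sum((cand - centers[j, ])^2) < min_d^2) {
            ok <- FALSE
            break
          }
        }
      }
      if (ok) {
        placed <- placed + 1
        centers[placed, ] <- cand
        if (placed == n_neurons) break
      }
    }
    if (placed < n_neurons) {
      stop("could not place ", n_neurons, " neurons with the minimum ",
           "spacing in a ", h, " x ", w, " frame (placed ", placed, ")")
    }
    covs <- lapply(seq_len(n_neurons), function(i) {
      r <- rot2(ang[i])
      r %*% diag(c(sig_major[i]^2, sig_minor[i]^2)) %*% t(r)
    })
    colnames(centers) <- c("x", "y")
    ch <- h + 2 * margin; cw <- w + 2 * margin
    texture <- matrix(texture_base, ch, cw)
    for (k in seq_along(texture_sd)) {
      f <- cpp_gauss_blur(matrix(rnorm(ch * cw), ch, cw),
                          texture_sigma[k], texture_sigma[k])
      texture <- texture + texture_sd[k] * f / sd(f)
    }
    texture <- pmax(texture, 0)
    structure(list(frame_shape = frame_shape, neuron_centers = centers,
                   neuron_covariances = covs, neuron_amplitudes = amp,
                   texture = texture, margin = margin,
                   seed = seed),
              class = "synthetic_scene")
  })
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %d neurons in %d x %d (seed %d)\n",
              nrow(x$neuron_centers), x$frame_shape[1], x$frame_shape[2],
              x$seed))
  invisible(x)
}

# transform of scene coordinates into a session frame: linear part about the
# frame centre plus a translation
session_transform <- function(pose, translation, frame_shape) {
  l <- linear_part(compose_affine(pose))
  ctr <- c((frame_shape[2] - 1) / 2, (frame_shape[1] - 1) / 2)
  e <- ctr + translation - as.vector(l %*% ctr)
  structure(cbind(l, e), class = "affine_transform")
}

#' Render one imaging session of a synthetic scene
#'
#' A subset of the scene's neurons is rendered analytically in the session
#' frame: each Gaussian blob's centre and covariance are pushed through the
#' session transform, so no resampling error enters the ground truth; the
#' scene's neuropil texture is warped by the same transform underneath.  The
#' intensity image then receives, in order, a smooth multiplicative
#' background gradient, Gaussian optical blur, additive Gaussian sensor
#' noise, and 8-bit quantization.  The paired ROI mask is rendered
#' noiselessly from the same subset and transform (blob support thresholded
#' at amplitude/5) and passed through [binarize_and_filter()].
#'
#' @param scene a `synthetic_scene`
#' @param pose an `affine_pose` for the session camera (tilt/spin/zoom)
#' @param translation `c(dx, dy)` pixels
#' @param active_fraction fraction of neurons active this session (ignored
#'   when `active_indices` is given)
#' @param active_indices explicit neuron indices to render
#' @param blur_sigma optical blur in pixels (0 = sharp)
#' @param background_amplitude relative amplitude of the low-frequency
#'   multiplicative brightness gradient (0 = flat; 0.4 = +/- 40 percent)
#' @param noise_sigma additive Gaussian noise sd in gray levels
#' @param seed integer driving subset choice, background phases and noise
#' @return a `session_render`: list with `image` (0..255), `mask`
#'   (`roi_mask`), `true_transform` (scene -> session `affine_transform`),
#'   `active_indices`, and the degradation parameters
#' @export
render_session <- function(scene, pose = affine_pose(), translation = c(0, 0),
                           active_fraction = 1, active_indices = NULL,
                           blur_sigma = 0, background_amplitude = 0,
                           noise_sigma = 0, seed = 1) {
  stopifnot(inherits(scene, "synthetic_scene"),
            active_fraction > 0, active_fraction <= 1)
  h <- scene$frame_shape[1]; w <- scene$frame_shape[2]
  n <- nrow(scene$neuron_centers)
  tr <- session_transform(pose, translation, scene$frame_shape)
  l <- linear_part(tr)
  with_seed(seed, {
    if (is.null(active_indices)) {
      k <- max(1, round(active_fraction * n))
      active_indices <- sort(sample.int(n, k))
    } else {
      active_indices <- sort(as.integer(active_indices))
    }
    # neuropil texture sampled through the session transform
    tex_map <- compose_transforms(
      affine_transform(e = scene$margin, f = scene$margin),
      invert_transform(tr))
    img <- cpp_warp_affine(scene$texture, unclass(tex_map), h, w, 1L,
                           mean(scene$texture))
    mask <- matrix(0L, h, w)
    lim <- blob_support_factor^2
    for (i in active_indices) {
      ctr <- transform_points(tr, scene$neuron_centers[i, , drop = FALSE])[1, ]
      cov <- l %*% scene$neuron_covariances[[i]] %*% t(l)
      pre <- solve(cov)
      r <- 3.5 * sqrt(max(eigen(cov, symmetric = TRUE, only.values = TRUE)$values))
      x0 <- max(0, floor(ctr[1] - r)); x1 <- min(w - 1, ceiling(ctr[1] + r))
      y0 <- max(0, floor(ctr[2] - r)); y1 <- min(h - 1, ceiling(ctr[2] + r))
      if (x0 > x1 || y0 > y1) next   # neuron fell outside this session's view
      xs <- x0:x1
      ys <- y0:y1
      dx <- outer(rep(1, length(ys)), xs - ctr[1])
      dy <- outer(ys - ctr[2], rep(1, length(xs)))
      q <- pre[1, 1] * dx^2 + 2 * pre[1, 2] * dx * dy + pre[2, 2] * dy^2
      win <- scene$neuron_amplitudes[i] * exp(-0.5 * q)
      img[ys + 1, xs + 1] <- img[ys + 1, xs + 1] + win
      mask[ys + 1, xs + 1][q <= lim] <- 255L
    }
    if (background_amplitude > 0) {
      nwave <- sample(2:4, 1)
      field <- matrix(0, h, w)
      xg <- matrix(0:(w - 1), h, w, byrow = TRUE)
      yg <- matrix(0:(h - 1), h, w)
      for (k in seq_len(nwave)) {
        fx <- runif(1, 0.3, 1.5) / w
        fy <- runif(1, 0.3, 1.5) / h
        ph <- runif(1, 0, 2 * pi)
        field <- field + cos(2 * pi * (fx * xg + fy * yg) + ph)
      }
      field <- field / max(abs(field))
      img <- img * (1 + background_amplitude * field)
    }
    if (blur_sigma > 0) img <- cpp_gauss_blur(img, blur_sigma, blur_sigma)
    if (noise_sigma > 0) img <- img + matrix(rnorm(h * w, 0, noise_sigma), h, w)
    img <- round(pmin(pmax(img, 0), 255))
    structure(list(image = img,
                   mask = binarize_and_filter(mask, 60),
                   true_transform = tr,
                   pose = pose, translation = translation,
                   active_indices = active_indices,
                   blur_sigma = blur_sigma,
                   background_amplitude = background_amplitude,
                   noise_sigma = noise_sigma,
                   seed = seed),
              class = "session_render")
  })
}

#' Benchmark suite configuration
#'
#' Defines the two difficulty strata.  "Easy" pairs have mild viewing-angle
#' change (latitude at most 15 degrees), high neuron overlap and no blur;
#' "stress" pairs combine a latitude of at least 35 degrees, at most 30
#' percent shared neurons, optical blur of at least 2 px on the moving
#' session, a strong brightness gradient and heavier noise — the regime in
#' which plain feature matching breaks down.
#'
#' @param n_pairs_easy,n_pairs_stress pairs per stratum
#' @param frame_shape frame size in pixels
#' @param n_neurons neurons per scene
#' @param easy,stress per-stratum parameter lists: `tilt_deg` (latitude
#'   range), `spin_deg`, `translation_px`, `overlap` (shared fraction of
#'   each session's neurons), `blur_sigma` (moving session), `background`
#'   and `noise_sigma`
#' @return a config list for [benchmark_suite()]
#' @export
benchmark_config <- function(n_pairs_easy = 10, n_pairs_stress = 10,
                             frame_shape = c(256, 256), n_neurons = 30,
                             easy = list(tilt_deg = c(5, 15),
                                         spin_deg = c(-10, 10),
                                         translation_px = c(-15, 15),
                                         overlap = c(0.8, 0.9),
                                         blur_sigma = c(0, 0),
                                         background = 0.10,
                                         noise_sigma = 2),
                             stress = list(tilt_deg = c(35, 42),
                                           spin_deg = c(-15, 15),
                                           translation_px = c(-15, 15),
                                           overlap = c(0.25, 0.30),
                                           blur_sigma = c(2, 2.5),
                                           background = 0.35,
                                           noise_sigma = 4)) {
  list(n_pairs_easy = n_pairs_easy, n_pairs_stress = n_pairs_stress,
       frame_shape = frame_shape, n_neurons = n_neurons,
       easy = easy, stress = stress)
}

#' Deterministic suite of synthetic session pairs
#'
#' Renders `n_pairs_easy + n_pairs_stress` template/moving session pairs
#' from independent scenes, stratified per [benchmark_config()].  The
#' template session is the frontal reference; the moving session carries
#' the viewing-angle change and degradations.  Every pair records its scene,
#' both renders, the shared neuron indices and the ground-truth moving ->
#' template transform.
#'
#' @param config see [benchmark_config()]
#' @param seed integer; the whole suite replays from it
#' @return list of pairs; each has `pair_id`, `stratum`, `scene`,
#'   `template`, `moving`, `shared_indices`, `true_transform`
#' @export
benchmark_suite <- function(config = benchmark_config(), seed = 0) {
  pairs <- list()
  plan <- c(rep("easy", config$n_pairs_easy),
            rep("stress", config$n_pairs_stress))
  n <- config$n_neurons
  with_seed(seed, {
    draws <- lapply(seq_along(plan), function(k) {
      p <- config[[plan[k]]]
      list(tilt_deg = runif(1, p$tilt_deg[1], p$tilt_deg[2]),
           spin = runif(1, p$spin_deg[1], p$spin_deg[2]) * pi / 180,
           phi = runif(1, 0, pi),
           trans = runif(2, p$translation_px[1], p$translation_px[2]),
           overlap = runif(1, p$overlap[1], p$overlap[2]),
           blur = runif(1, p$blur_sigma[1], p$blur_sigma[2]),
           background = p$background,
           noise = p$noise_sigma,
           seeds = sample.int(100000, 4))
    })
  })
  for (k in seq_along(plan)) {
    d <- draws[[k]]
    scene <- generate_scene(n, config$frame_shape, seed = d$seeds[1])
    # split neurons into shared + per-session exclusives
    m <- floor(n / (2 - d$overlap))          # neurons per session
    s <- round(d$overlap * m)                # shared neurons
    if (2 * m - s > n) m <- floor((n + s) / 2)
    perm <- with_seed(d$seeds[2], sample.int(n))
    shared <- perm[seq_len(s)]
    extra_t <- perm[s + seq_len(m - s)]
    extra_m <- perm[m + seq_len(m - s)]
    tpl <- render_session(scene,
                          pose = affine_pose(),
                          translation = c(0, 0),
                          active_indices = c(shared, extra_t),
                          blur_sigma = 0,
                          background_amplitude = d$background / 2,
                          noise_sigma = 2,
                          seed = d$seeds[3])
    mov_pose <- affine_pose(psi = d$spin,
                            tilt = 1 / cos(d$tilt_deg * pi / 180),
                            phi = d$phi)
    mov <- render_session(scene,
                          pose = mov_pose,
                          translation = d$trans,
                          active_indices = c(shared, extra_m),
                          blur_sigma = d$blur,
                          background_amplitude = d$background,
                          noise_sigma = d$noise,
                          seed = d$seeds[4])
    true_tr <- compose_transforms(tpl$true_transform,
                                  invert_transform(mov$true_transform))
    pairs[[k]] <- list(pair_id = k, stratum = plan[k], scene = scene,
                       template = tpl, moving = mov,
                       shared_indices = sort(shared),
                       true_transform = true_tr,
                       params = d)
  }
  pairs
}

#' Masks of the neurons common to a benchmark pair
#'
#' Re-renders the noiseless ROI masks of both sessions restricted to the
#' pair's shared neurons — the synthetic counterpart of the curated
#' common-neuron masks used to score an alignment.
#'
#' @param pair one element of [benchmark_suite()]'s result
#' @return list with `template` and `moving` `roi_mask`s
#' @export
pair_common_masks <- function(pair) {
  re <- function(render) {
    render_session(pair$scene, pose = render$pose,
                   translation = render$translation,
                   active_indices = pair$shared_indices,
                   seed = render$seed)$mask
  }
  list(template = re(pair$template), moving = re(pair$moving))
}
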