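# Shared fixtures, all generated in code.

# image of k bright anisotropic Gaussian blobs on a dark background
blob_image <- function(n = 256, k = 10, seed = 1, base = 20) {
  set.seed(seed)
  img <- matrix(base, n, n)
  ctr <- cbind(runif(k, 40, n - 40), runif(k, 40, n - 40))
  for (i in seq_len(k)) {
    s1 <- runif(1, 2.6, 3.6); s2 <- runif(1, 2.6, 3.6); th <- runif(1, 0, pi)
    r <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    p <- solve(r %*% diag(c(s1^2, s2^2)) %*% t(r))
    amp <- runif(1, 120, 220)
    xs <- max(1, round(ctr[i, 1] - 15)):min(n, round(ctr[i, 1] + 15))
    ys <- max(1, round(ctr[i, 2] - 15)):min(n, round(ctr[i, 2] + 15))
    g <- expand.grid(x = xs, y = ys)
    dx <- g$x - ctr[i, 1]; dy <- g$y - ctr[i, 2]
    v <- amp * exp(-0.5 * (p[1, 1] * dx^2 + 2 * p[1, 2] * dx * dy + p[2, 2] * dy^2))
    img[cbind(g$y, g$x)] <- img[cbind(g$y, g$x)] + v
  }
  list(image = pmin(img, 255), centers = ctr)  # centers are 1-based (x, y)
}

# random 2x2 matrix with positive determinant
random_posdet_matrix <- function() {
  repeat {
    m <- matrix(rnorm(4), 2)
    d <- m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1]
    if (abs(d) > 1e-3) {
      if (d < 0) m[, 1] <- -m[, 1]
      return(m)
    }
  }
}

all_backends <- c("SIFT", "SURF", "AKAZE", "BRISK", "ORB")

# cache shared between the heavyweight acceptance blocks
.accept_cache <- new.env(parent = emptyenv())

# small rendered session pair with known ground truth
tiny_pair <- function(seed = 7, tilt_deg = 25, spin_deg = 8,
                      translation = c(10, -6), blur = 1, noise = 2,
                      background = 0.15, n_neurons = 20) {
  scene <- generate_scene(n_neurons, c(192, 192), seed = seed)
  tpl <- render_session(scene, seed = seed + 1, noise_sigma = 2,
                        background_amplitude = background / 2)
  mov <- render_session(scene,
                        pose = affine_pose(psi = spin_deg * pi / 180,
                                           tilt = 1 / cos(tilt_deg * pi / 180),
                                           phi = 0.9),
                        translation = translation, blur_sigma = blur,
                        background_amplitude = background,
                        noise_sigma = noise, seed = seed + 2)
  list(scene = scene, template = tpl, moving = mov,
       true_transform = compose_transforms(
         tpl$true_transform, invert_transform(mov$true_transform)))
}
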