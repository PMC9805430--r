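# Small seeded fixtures shared across the suite. All generated in code; the
# tiny geometry keeps the unit tests fast while exercising every code path.

tiny_spec <- function(seed = 1L, ...) {
  phantom_spec(volume_shape = c(64L, 32L, 8L),
               n_druse_clusters = 1L, n_foci = 1L, n_sdd = 0L,
               druse_radius_range = c(3, 5), focus_radius_range = c(1, 2),
               noise_sigma = 0.05,
               transform_jitter = list(translate = 5, rotate = 2,
                                       projective = 2e-5),
               conversion_margin = 1L, seed = seed, ...)
}

small_spec <- function(seed = 1L, ...) {
  phantom_spec(volume_shape = c(64L, 64L, 16L),
               n_druse_clusters = 2L, n_foci = 2L, n_sdd = 1L,
               druse_radius_range = c(5, 9), focus_radius_range = c(2, 3),
               noise_sigma = 0.08,
               transform_jitter = list(translate = 8, rotate = 3,
                                       projective = 5e-5),
               conversion_margin = 2L, seed = seed, ...)
}

# identity-misalignment variant of the tiny spec (for exact mask identities)
identity_spec <- function(seed = 1L, margin = 0L) {
  phantom_spec(volume_shape = c(64L, 32L, 8L),
               n_druse_clusters = 1L, n_foci = 2L, n_sdd = 0L,
               druse_radius_range = c(3, 5), focus_radius_range = c(1, 2),
               noise_sigma = 0.05,
               transform_jitter = list(translate = 0, rotate = 0,
                                       projective = 0),
               conversion_margin = margin, seed = seed)
}

random_homography <- function() {
  th <- stats::runif(1, -0.2, 0.2)
  s <- stats::runif(1, 0.8, 1.2)
  m <- rbind(c(s * cos(th), -s * sin(th), stats::runif(1, -20, 20)),
             c(s * sin(th), s * cos(th), stats::runif(1, -20, 20)),
             c(stats::runif(1, -1e-4, 1e-4), stats::runif(1, -1e-4, 1e-4), 1))
  planar_transform(m)
}

# n random points in general position (no 3 nearly collinear)
random_points <- function(n, lim = 300) {
  repeat {
    p <- cbind(stats::runif(n, 10, lim), stats::runif(n, 10, lim))
    ok <- TRUE
    if (n >= 3) {
      idx <- utils::combn(n, 3)
      for (j in seq_len(ncol(idx))) {
        a <- p[idx[1, j], ]; b <- p[idx[2, j], ]; c <- p[idx[3, j], ]
        ar <- abs((b[1] - a[1]) * (c[2] - a[2]) -
                    (c[1] - a[1]) * (b[2] - a[2])) / 2
        if (ar < 100) { ok <- FALSE; break }
      }
    }
    if (ok) return(p)
  }
}

rel_matrix_error <- function(a, b) {
  a <- a / a[3, 3]; b <- b / b[3, 3]
  norm(a - b, "F") / norm(b, "F")
}

random_layers <- function(w, d, h) {
  ilm <- matrix(sample(2:10, w * d, TRUE), w, d)
  rpe <- ilm + matrix(sample(5:15, w * d, TRUE), w, d)
  cs <- rpe + matrix(sample(3:8, w * d, TRUE), w, d)
  layer_boundaries(ilm, rpe, cs, height = h)
}

tiny_unet <- function(depth = 2L, base = 2L, in_shape = c(16L, 16L),
                      seed = 1L, ...) {
  build_unet(unet_config(depth = depth, base_channels = base,
                         in_shape = in_shape, seed = seed, ...))
}
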