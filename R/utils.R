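# Shared raster and RNG helpers.
#
# Conventions used throughout the package:
#  * images are numeric matrices [row, col] with values in [0, 1];
#  * points are (x, y) with x = column, y = row, 0-based, pixel centers at
#    integer coordinates (the convention of the keypoint JSON interchange);
#  * en-face maps are (width x depth) matrices, width along rows;
#  * OCT volumes are (height x width x depth) arrays, one B-scan per slice.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded generators do not disturb the global stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Sample an image at continuous 0-based (x, y); out-of-frame samples are 0.
bilinear_sample <- function(img, x, y) {
  h <- nrow(img); w <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  px <- function(ix, iy) {
    inb <- ix >= 0 & ix < w & iy >= 0 & iy < h
    v <- numeric(length(ix))
    v[inb] <- img[iy[inb] + ix[inb] * h + 1]
    v
  }
  px(x0, y0) * (1 - fx) * (1 - fy) + px(x0 + 1, y0) * fx * (1 - fy) +
    px(x0, y0 + 1) * (1 - fx) * fy + px(x0 + 1, y0 + 1) * fx * fy
}

nearest_sample <- function(img, x, y) {
  h <- nrow(img); w <- ncol(img)
  ix <- floor(x + 0.5); iy <- floor(y + 0.5)
  inb <- ix >= 0 & ix < w & iy >= 0 & iy < h
  v <- numeric(length(ix))
  v[inb] <- img[iy[inb] + ix[inb] * h + 1]
  v
}

# Binary dilation of a logical matrix by a disc of radius r (r = 0 is identity).
dilate_disc <- function(mask, r) {
  stopifnot(r >= 0)
  mask <- mask > 0
  if (r == 0) return(mask)
  h <- nrow(mask); w <- ncol(mask)
  out <- mask
  for (dy in -r:r) {
    for (dx in -r:r) {
      if (dy == 0 && dx == 0) next
      if (dy * dy + dx * dx > r * r) next
      sr <- max(1, 1 - dy):min(h, h - dy)
      sc <- max(1, 1 - dx):min(w, w - dx)
      out[sr + dy, sc + dx] <- out[sr + dy, sc + dx] | mask[sr, sc]
    }
  }
  out
}

erode_disc <- function(mask, r) !dilate_disc(!(mask > 0), r)

# Smooth random surface over a (w x d) grid: base + sum of low-frequency
# sinusoids with seeded coefficients; used for retinal layer geometry.
smooth_surface <- function(w, d, base, amp, n_waves = 3L) {
  ww <- (seq_len(w) - 1) / max(w - 1, 1)
  dd <- (seq_len(d) - 1) / max(d - 1, 1)
  s <- matrix(base, w, d)
  for (k in seq_len(n_waves)) {
    fx <- stats::runif(1, 0.5, 2.5); fy <- stats::runif(1, 0.5, 2.5)
    px <- stats::runif(1, 0, 2 * pi); py <- stats::runif(1, 0, 2 * pi)
    a <- amp * stats::runif(1, 0.3, 1) / k
    s <- s + a * outer(sin(2 * pi * fx * ww + px), sin(2 * pi * fy * dd + py))
  }
  s
}

as_binary <- function(m) {
  storage.mode(m) <- "double"
  (m > 0.5) * 1
}

dice_coef <- function(a, b) {
  a <- a > 0; b <- b > 0
  sa <- sum(a); sb <- sum(b)
  if (sa == 0 && sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}
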