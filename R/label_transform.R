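# Cross-modal label transfer: keypoint homography registration of follow-up
# FAF annotations into baseline en-face coordinates, and extrusion of the
# registered 2D atrophy mask into per-B-scan ground truth between the ILM and
# choroid-sclera boundaries.

#' Keypoint correspondence set
#'
#' A set of manually (or, for phantoms, synthetically) selected point
#' correspondences between a follow-up FAF image and the baseline en-face
#' frame. Points are (x, y) with x = column and y = row, 0-based.
#'
#' @param src n x 2 matrix of source points (follow-up FAF frame).
#' @param dst n x 2 matrix of destination points (baseline en-face frame).
#' @return An object of class `keypoint_set`.
#' @export
keypoint_set <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  storage.mode(src) <- storage.mode(dst) <- "double"
  dimnames(src) <- dimnames(dst) <- NULL
  if (ncol(src) != 2 || ncol(dst) != 2 || nrow(src) != nrow(dst)) {
    stop("keypoints must be two n x 2 matrices of matching size")
  }
  structure(list(src = src, dst = dst), class = "keypoint_set")
}

#' @export
print.keypoint_set <- function(x, ...) {
  cat(sprintf("<keypoint_set: %d correspondences>\n", nrow(x$src)))
  invisible(x)
}

#' Planar projective transform
#'
#' A 3 x 3 homography mapping homogeneous (x, y, 1) points from the follow-up
#' FAF frame into the baseline en-face frame. The matrix is normalized so the
#' bottom-right entry is 1 whenever it is nonzero.
#'
#' @param m 3 x 3 numeric matrix.
#' @return An object of class `planar_transform`.
#' @export
planar_transform <- function(m) {
  m <- as.matrix(m)
  if (!all(dim(m) == c(3, 3)) || !all(is.finite(m))) {
    stop("a planar transform is a finite 3 x 3 matrix")
  }
  if (abs(m[3, 3]) > .Machine$double.eps) m <- m / m[3, 3]
  if (abs(det(m)) < 1e-12) stop("planar transform is not invertible")
  structure(list(matrix = m), class = "planar_transform")
}

#' @export
print.planar_transform <- function(x, ...) {
  cat("<planar_transform>\n")
  print(signif(x$matrix, 6))
  invisible(x)
}

#' Apply a planar transform to points
#'
#' @param t A `planar_transform`.
#' @param pts n x 2 matrix of (x, y) points.
#' @return n x 2 matrix of mapped points.
#' @export
transform_points <- function(t, pts) {
  stopifnot(inherits(t, "planar_transform"))
  pts <- matrix(as.numeric(pts), ncol = 2)
  p <- t$matrix %*% rbind(t(pts), 1)
  cbind(p[1, ] / p[3, ], p[2, ] / p[3, ])
}

#' Invert a planar transform
#'
#' @param t A `planar_transform`.
#' @return The inverse `planar_transform`.
#' @export
invert_transform <- function(t) {
  stopifnot(inherits(t, "planar_transform"))
  planar_transform(solve(t$matrix))
}

#' Fit a homography to keypoint correspondences
#'
#' Estimates the planar projective transform mapping source (follow-up FAF)
#' points onto destination (baseline en-face) points by the normalized direct
#' linear transform: both point sets are translated to their centroid and
#' scaled to mean distance sqrt(2), the 2n x 9 homogeneous system is solved by
#' singular value decomposition, and the similarity normalizations are undone.
#' With four or more noiseless, consistent pairs the fit is exact.
#'
#' @param kp A [keypoint_set()] with at least 4 pairs.
#' @return A [planar_transform()].
#' @export
fit_planar_transform <- function(kp) {
  stopifnot(inherits(kp, "keypoint_set"))
  n <- nrow(kp$src)
  if (n < 4) stop("homography fitting needs at least 4 keypoint pairs")
  normalize <- function(p) {
    ctr <- colMeans(p)
    q <- sweep(p, 2, ctr)
    md <- mean(sqrt(rowSums(q^2)))
    s <- if (md > 0) sqrt(2) / md else 1
    T <- rbind(c(s, 0, -s * ctr[1]), c(0, s, -s * ctr[2]), c(0, 0, 1))
    list(T = T, p = q * s)
  }
  ns <- normalize(kp$src); nd <- normalize(kp$dst)
  A <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    x <- ns$p[i, 1]; y <- ns$p[i, 2]
    u <- nd$p[i, 1]; v <- nd$p[i, 2]
    A[2 * i - 1, ] <- c(-x, -y, -1, 0, 0, 0, u * x, u * y, u)
    A[2 * i, ] <- c(0, 0, 0, -x, -y, -1, v * x, v * y, v)
  }
  sv <- svd(A, nu = 0, nv = 9)
  # rank deficiency (e.g. 3 collinear of 4 points) leaves a 2+ dimensional
  # null space: the two smallest singular values are then both ~0
  if (n == 4 && sv$d[8] < 1e-8 * max(sv$d[1], 1)) {
    stop("degenerate keypoint configuration: system is rank deficient")
  }
  H <- matrix(sv$v[, 9], 3, 3, byrow = TRUE)
  H <- solve(nd$T) %*% H %*% ns$T
  planar_transform(H)
}

#' Warp an image under a planar transform
#'
#' Resamples by inverse mapping: each output pixel is looked up at the
#' transform's preimage. Grayscale images use bilinear interpolation, binary
#' masks nearest-neighbor (re-binarized); samples falling outside the source
#' frame are 0.
#'
#' @param img Numeric matrix.
#' @param t A [planar_transform()] from source to destination coordinates.
#' @param out_shape Integer (rows, cols) of the output; default `dim(img)`.
#' @param method `"bilinear"` or `"nearest"`.
#' @return Numeric matrix of shape `out_shape`.
#' @export
warp_image <- function(img, t, out_shape = dim(img),
                       method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  stopifnot(inherits(t, "planar_transform"))
  ti <- solve(t$matrix)
  h <- out_shape[1]; w <- out_shape[2]
  xg <- rep(0:(w - 1), each = h)
  yg <- rep(0:(h - 1), w)
  p <- ti %*% rbind(xg, yg, 1)
  sx <- p[1, ] / p[3, ]; sy <- p[2, ] / p[3, ]
  v <- if (method == "bilinear") bilinear_sample(img, sx, sy)
       else nearest_sample(img, sx, sy)
  matrix(v, h, w)
}

#' Resize an image
#'
#' Separable rescaling with the half-pixel-center convention
#' (`src = (dst + 0.5) * n_src / n_dst - 0.5`), bilinear for intensities and
#' nearest-neighbor for masks. Integer upscaling under `"nearest"` replicates
#' pixels into exact blocks, and the matching integer downscale inverts it.
#'
#' @param img Numeric matrix.
#' @param out_shape Integer (rows, cols).
#' @param method `"bilinear"` or `"nearest"`.
#' @return Numeric matrix of shape `out_shape`.
#' @export
resize_image <- function(img, out_shape, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  h <- out_shape[1]; w <- out_shape[2]
  xg <- rep(0:(w - 1), each = h)
  yg <- rep(0:(h - 1), w)
  sx <- (xg + 0.5) * ncol(img) / w - 0.5
  sy <- (yg + 0.5) * nrow(img) / h - 0.5
  if (method == "bilinear") {
    # clamp so border pixels extend rather than fade to zero
    sx <- pmin(pmax(sx, 0), ncol(img) - 1)
    sy <- pmin(pmax(sy, 0), nrow(img) - 1)
    matrix(bilinear_sample(img, sx, sy), h, w)
  } else {
    sx <- pmin(pmax(sx, 0), ncol(img) - 1)
    sy <- pmin(pmax(sy, 0), nrow(img) - 1)
    matrix(nearest_sample(img, sx, sy), h, w)
  }
}

#' En-face mean-intensity projection of an OCT volume
#'
#' Collapses the axial (height) dimension by the arithmetic mean, giving a
#' (width x depth) en-face map with values on the intensity scale of the
#' volume.
#'
#' @param vol Numeric array (height x width x depth).
#' @return (width x depth) numeric matrix.
#' @export
project_volume <- function(vol) {
  stopifnot(length(dim(vol)) == 3)
  d <- dim(vol)
  m <- matrix(vol, d[1], d[2] * d[3])
  matrix(colMeans(m), d[2], d[3])
}

#' Register a follow-up annotation into baseline coordinates
#'
#' Fits the keypoint homography and warps the binary follow-up GA mask into
#' the baseline en-face frame with nearest-neighbor resampling.
#'
#' @param followup_mask Binary matrix in follow-up FAF coordinates.
#' @param kp A [keypoint_set()] (source = follow-up, destination = baseline).
#' @param out_shape Output (rows, cols); default `dim(followup_mask)`.
#' @return Binary matrix in baseline coordinates.
#' @export
register_annotation <- function(followup_mask, kp,
                                out_shape = dim(followup_mask)) {
  t <- fit_planar_transform(kp)
  as_binary(warp_image(followup_mask, t, out_shape, method = "nearest"))
}

#' Layer boundary container
#'
#' Per-A-scan retinal boundary rows: inner limiting membrane (ILM), retinal
#' pigment epithelium (RPE) and choroid-sclera junction (C-S), each a
#' (width x depth) integer matrix of 0-based row indices with
#' `ilm < rpe < cs` everywhere.
#'
#' @param ilm,rpe,cs (width x depth) matrices of row indices.
#' @param height Axial extent of the volume the rows index into.
#' @return An object of class `layer_boundaries`.
#' @export
layer_boundaries <- function(ilm, rpe, cs, height) {
  ilm <- round(ilm); rpe <- round(rpe); cs <- round(cs)
  if (!all(dim(ilm) == dim(cs)) || !all(dim(ilm) == dim(rpe))) {
    stop("layer boundary matrices must share their (width x depth) shape")
  }
  if (any(ilm < 0) || any(cs >= height) || any(ilm >= rpe) || any(rpe >= cs)) {
    stop("layer ordering violated: need 0 <= ilm < rpe < cs < height")
  }
  structure(list(ilm = ilm, rpe = rpe, cs = cs, height = as.integer(height)),
            class = "layer_boundaries")
}

#' Extrude an en-face annotation into per-B-scan masks
#'
#' For every positive en-face pixel (w, d), marks rows
#' `ilm(w, d) .. cs(w, d)` (inclusive) of column w in B-scan d positive; all
#' other voxels are negative. This turns a registered 2D GA annotation into
#' the 3D ground truth used to train the per-B-scan segmentation network.
#'
#' @param enface_mask Binary (width x depth) matrix, already resampled to the
#'   volume's lateral grid.
#' @param layers A [layer_boundaries()] matching the volume.
#' @param volume_shape Integer (height, width, depth).
#' @return Binary array (height x width x depth).
#' @export
extrude_label <- function(enface_mask, layers, volume_shape) {
  stopifnot(inherits(layers, "layer_boundaries"))
  h <- volume_shape[1]; w <- volume_shape[2]; d <- volume_shape[3]
  if (!all(dim(layers$ilm) == c(w, d))) {
    stop("layer boundary shape does not match the volume's width x depth")
  }
  if (!all(dim(enface_mask) == c(w, d))) {
    stop("en-face mask must be width x depth of the target volume")
  }
  stack <- array(0, c(h, w, d))
  rows <- seq_len(h) - 1L
  for (di in seq_len(d)) {
    on <- enface_mask[, di] > 0
    if (!any(on)) next
    sl <- outer(rows, layers$ilm[, di], ">=") & outer(rows, layers$cs[, di], "<=")
    sl[, !on] <- FALSE
    stack[, , di] <- sl * 1
  }
  stack
}

#' Collapse a B-scan label stack back to its en-face support
#'
#' @param stack Binary array (height x width x depth).
#' @return Binary (width x depth) matrix: 1 where any voxel in the column is
#'   positive.
#' @export
collapse_label <- function(stack) {
  d <- dim(stack)
  (matrix(colSums(matrix(stack, d[1], d[2] * d[3]) > 0), d[2], d[3]) > 0) * 1
}
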