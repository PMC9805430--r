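# Seeded retinal phantom: synthetic baseline OCT volumes with layered
# anatomy, three lesion classes (druse clusters, hyper-reflective foci,
# subretinal drusenoid deposits), vessel fiducials, baseline/follow-up
# FAF-like en-face images under a known planar misalignment, and a known
# GA-conversion rule (druse clusters convert; isolated foci and SDD do not).

#' Phantom generation parameters
#'
#' Defines one synthetic patient case: volume geometry, lesion census, lesion
#' sizes, speckle level, the magnitude of the baseline/follow-up planar
#' misalignment, and the en-face dilation applied to converting lesion
#' footprints to form the follow-up GA annotation.
#'
#' Lesion radii are measured in width-axis en-face pixels; the depth axis is
#' scaled by the volume's width/depth ratio so footprints are physically
#' isotropic on the (square) en-face field.
#'
#' @param volume_shape Integer (height, width, depth) of the OCT volume.
#' @param n_druse_clusters,n_foci,n_sdd Lesion counts (druse clusters convert
#'   to GA; hyper-reflective foci and SDD do not).
#' @param druse_radius_range,focus_radius_range Min/max lesion radius, px.
#' @param noise_sigma Multiplicative speckle fraction in `[0, 1]`.
#' @param transform_jitter List with `translate` (max px), `rotate` (max
#'   degrees) and `projective` (max perturbation of the homography's bottom
#'   row) for the follow-up misalignment.
#' @param conversion_margin En-face dilation radius (px) applied to converting
#'   footprints when forming the follow-up GA annotation.
#' @param seed Integer seed; the phantom is a deterministic function of the
#'   spec including this seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(volume_shape = c(256L, 128L, 32L),
                         n_druse_clusters = 3L, n_foci = 3L, n_sdd = 2L,
                         druse_radius_range = c(7, 12),
                         focus_radius_range = c(2, 4),
                         noise_sigma = 0.08,
                         transform_jitter = list(translate = 10, rotate = 4,
                                                 projective = 5e-5),
                         conversion_margin = 2L,
                         seed = 1L) {
  volume_shape <- as.integer(volume_shape)
  stopifnot(length(volume_shape) == 3, all(volume_shape > 0),
            n_druse_clusters >= 0, n_foci >= 0, n_sdd >= 0,
            druse_radius_range[1] <= druse_radius_range[2],
            focus_radius_range[1] <= focus_radius_range[2],
            noise_sigma >= 0, noise_sigma <= 1, conversion_margin >= 0)
  structure(list(volume_shape = volume_shape,
                 n_druse_clusters = as.integer(n_druse_clusters),
                 n_foci = as.integer(n_foci), n_sdd = as.integer(n_sdd),
                 druse_radius_range = as.numeric(druse_radius_range),
                 focus_radius_range = as.numeric(focus_radius_range),
                 noise_sigma = noise_sigma,
                 transform_jitter = transform_jitter,
                 conversion_margin = as.integer(conversion_margin),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Elliptical en-face footprint support: max over discs of
# 1 - ((w-cw)^2 + ((d-cd)*asp)^2) / r^2, clipped at 0. `discs` is a matrix
# with columns cw, cd, r (0-based centers, width-px radii).
lesion_support <- function(w, d, discs, asp) {
  s <- matrix(0, w, d)
  wg <- matrix(0:(w - 1), w, d)
  dg <- matrix(0:(d - 1), w, d, byrow = TRUE)
  for (i in seq_len(nrow(discs))) {
    v <- 1 - ((wg - discs[i, 1])^2 + ((dg - discs[i, 2]) * asp)^2) / discs[i, 3]^2
    s <- pmax(s, v)
  }
  pmax(s, 0)
}

place_lesion <- function(w, d, asp, occupied, kind, radius_range, sep) {
  for (attempt in 1:200) {
    r <- stats::runif(1, radius_range[1], radius_range[2])
    rd <- r / asp
    if (r + 1 >= w - r - 2 || rd + 1 >= d - rd - 2) next  # cannot fit at all
    cw <- stats::runif(1, r + 1, w - r - 2)
    cd <- stats::runif(1, rd + 1, d - rd - 2)
    if (kind == "druse_cluster") {
      nd <- sample(2:4, 1)
      discs <- t(vapply(seq_len(nd), function(i) {
        c(cw + stats::runif(1, -0.5, 0.5) * r,
          cd + stats::runif(1, -0.5, 0.5) * rd,
          r * stats::runif(1, 0.55, 1))
      }, numeric(3)))
    } else {
      discs <- matrix(c(cw, cd, r), 1)
    }
    s <- lesion_support(w, d, discs, asp)
    fp <- s > 0
    if (!any(fp)) next
    clear <- !any(dilate_disc(fp, sep) & occupied)
    inside <- !any(fp[c(1, w), ]) && !any(fp[, c(1, d)])
    if (clear && inside) return(list(support = s, footprint = fp, discs = discs))
  }
  stop(sprintf(
    "could not place %s lesion without overlap after 200 attempts; reduce counts or radii",
    kind))
}

draw_misalignment <- function(jit, size = 512) {
  ctr <- (size - 1) / 2
  for (attempt in 1:50) {
    th <- stats::runif(1, -jit$rotate, jit$rotate) * pi / 180
    tx <- stats::runif(1, -jit$translate, jit$translate)
    ty <- stats::runif(1, -jit$translate, jit$translate)
    g <- stats::runif(2, -jit$projective, jit$projective)
    R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
    M <- diag(3)
    M[1:2, 1:2] <- R
    M[1:2, 3] <- c(ctr, ctr) - R %*% c(ctr, ctr) + c(tx, ty)
    M[3, 1:2] <- g
    t <- planar_transform(M)
    corners <- rbind(c(0, 0), c(size - 1, 0), c(0, size - 1),
                     c(size - 1, size - 1))
    disp <- sqrt(rowSums((transform_points(t, corners) - corners)^2))
    if (max(disp) < size / 8) return(t)
  }
  stop("could not draw a bounded misalignment; reduce transform_jitter")
}

# Quadratic Bezier vessel curves on the FAF frame; returns the rasterized
# vessel mask and the fiducial points (x, y) lying on the curves.
draw_vessels <- function(size = 512, n_curves = 6) {
  mask <- matrix(FALSE, size, size)
  fid <- NULL
  ts <- seq(0, 1, length.out = 300)
  for (k in seq_len(n_curves)) {
    P <- matrix(stats::runif(6, 0.05 * size, 0.95 * size), 3, 2)
    x <- (1 - ts)^2 * P[1, 1] + 2 * ts * (1 - ts) * P[2, 1] + ts^2 * P[3, 1]
    y <- (1 - ts)^2 * P[1, 2] + 2 * ts * (1 - ts) * P[2, 2] + ts^2 * P[3, 2]
    for (off in list(c(0, 0), c(1, 0), c(0, 1), c(-1, 0), c(0, -1))) {
      ix <- round(x) + off[1]; iy <- round(y) + off[2]
      ok <- ix >= 0 & ix < size & iy >= 0 & iy < size
      mask[cbind(iy[ok] + 1, ix[ok] + 1)] <- TRUE
    }
    tt <- c(0.2, 0.35, 0.5, 0.65, 0.8)
    fx <- (1 - tt)^2 * P[1, 1] + 2 * tt * (1 - tt) * P[2, 1] + tt^2 * P[3, 1]
    fy <- (1 - tt)^2 * P[1, 2] + 2 * tt * (1 - tt) * P[2, 2] + tt^2 * P[3, 2]
    fid <- rbind(fid, cbind(fx, fy))
  }
  list(mask = mask, fiducials = fid)
}

#' Generate one synthetic patient case
#'
#' Renders a layered baseline OCT volume (vitreous, inner retina, RPE band,
#' choroid between RPE and C-S, sclera) with multiplicative speckle, places
#' the requested lesions on disjoint en-face footprints (druse clusters as
#' dome-shaped RPE elevations, foci as bright intraretinal blobs, SDD as thin
#' bright deposits above the RPE), derives baseline and follow-up FAF-like
#' images sharing vessel anatomy, and forms the follow-up GA annotation as the
#' union of converting (druse-cluster) footprints dilated by the conversion
#' margin, warped into the follow-up frame by the inverse of the drawn
#' misalignment.
#'
#' The result is a deterministic function of the spec, including its seed.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `phantom_case` with elements `oct`,
#'   `baseline_faf`, `followup_faf`, `followup_ga_mask` (512 x 512, follow-up
#'   frame), `true_transform` (follow-up to baseline), `keypoints`, `layers`,
#'   `lesions`, `ga_enface` (width x depth truth in baseline coordinates) and
#'   `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    h <- spec$volume_shape[1]; w <- spec$volume_shape[2]
    d <- spec$volume_shape[3]
    asp <- w / d

    ilm <- smooth_surface(w, d, 0.18 * h, 0.03 * h)
    rpe <- smooth_surface(w, d, 0.62 * h, 0.015 * h)
    cs <- rpe + 0.20 * h + smooth_surface(w, d, 0, 0.01 * h)
    ilm <- pmin(pmax(round(ilm), 1), h - 30)
    rpe <- pmin(pmax(round(rpe), ilm + 20), h - 15)
    cs <- pmin(pmax(round(cs), rpe + 8), h - 2)
    layers <- layer_boundaries(ilm, rpe, cs, h)

    sep <- spec$conversion_margin + 2L
    occupied <- matrix(FALSE, w, d)
    lesions <- list()
    add <- function(kind, rng) {
      pl <- place_lesion(w, d, asp, occupied, kind, rng, sep)
      occupied <<- occupied | pl$footprint
      anchors <- matrix(NA_real_, w, d)
      lesions[[length(lesions) + 1]] <<- list(
        kind = kind, support = pl$support,
        enface_footprint = pl$footprint * 1, axial_anchor = anchors,
        converts = identical(kind, "druse_cluster"))
    }
    for (i in seq_len(spec$n_druse_clusters)) add("druse_cluster", spec$druse_radius_range)
    for (i in seq_len(spec$n_foci)) add("hyper_reflective_focus", spec$focus_radius_range)
    for (i in seq_len(spec$n_sdd)) add("sdd", spec$druse_radius_range)

    # axial anchors and druse elevation field
    dome <- matrix(0, w, d)
    for (j in seq_along(lesions)) {
      les <- lesions[[j]]
      fp <- les$enface_footprint > 0
      anc <- matrix(NA_real_, w, d)
      if (les$kind == "druse_cluster") {
        hmax <- stats::runif(1, 0.08, 0.14) * h
        dome_j <- hmax * sqrt(les$support)
        dome <- dome + dome_j
        anc[fp] <- rpe[fp] - dome_j[fp]
      } else if (les$kind == "hyper_reflective_focus") {
        frac <- stats::runif(1, 0.35, 0.65)
        anc[fp] <- round(ilm[fp] + frac * (rpe[fp] - ilm[fp]))
        lesions[[j]]$radius <- stats::runif(1, spec$focus_radius_range[1],
                                            spec$focus_radius_range[2])
      } else {
        anc[fp] <- rpe[fp] - 5
      }
      lesions[[j]]$axial_anchor <- round(anc)
    }
    rpe_eff <- pmax(rpe - round(dome), ilm + 4)

    vol <- array(0, c(h, w, d))
    rows <- seq_len(h) - 1L
    for (di in seq_len(d)) {
      ild <- ilm[, di]; rpd <- rpe[, di]; red <- rpe_eff[, di]; csd <- cs[, di]
      sl <- matrix(0.06, h, w)
      ge <- function(v) outer(rows, v, ">=")
      lt <- function(v) outer(rows, v, "<")
      sl[ge(ild) & lt(red - 2)] <- 0.42
      sl[ge(red - 2) & lt(red + 2)] <- 0.85             # (possibly elevated) RPE band
      sl[ge(red + 2) & lt(rpd + 2)] <- 0.60             # sub-RPE druse material
      sl[ge(rpd + 2) & lt(csd + 1)] <- 0.30             # choroid
      sl[ge(csd + 1)] <- 0.12                           # sclera
      for (les in lesions) {
        fp <- which(les$enface_footprint[, di] > 0)
        if (!length(fp)) next
        if (les$kind == "sdd") {
          for (ww in fp) {
            rr <- (rpe[ww, di] - 7):(rpe[ww, di] - 4)
            sl[rr + 1, ww] <- 0.90
          }
        } else if (les$kind == "hyper_reflective_focus") {
          for (ww in fp) {
            rh <- max(2, les$radius * sqrt(les$support[ww, di]))
            anc <- les$axial_anchor[ww, di]
            rr <- max(0, anc - rh):min(h - 1, anc + rh)
            sl[rr + 1, ww] <- 0.95
          }
        }
      }
      vol[, , di] <- sl
    }
    if (spec$noise_sigma > 0) {
      vol <- vol * (1 + spec$noise_sigma * stats::rnorm(length(vol)))
    }
    vol <- pmin(pmax(vol, 0), 1)
    vol <- round(vol * 65535) / 65535   # 16-bit grid so disk round-trips are exact

    # en-face GA truth in baseline coordinates (width x depth, then 512 frame)
    ga_enface <- matrix(0, w, d)
    for (les in lesions) {
      if (les$converts) ga_enface <- ga_enface + les$enface_footprint
    }
    ga_enface <- dilate_disc(ga_enface > 0, spec$conversion_margin) * 1
    ga512 <- resize_image(ga_enface, c(512, 512), method = "nearest")

    ves <- draw_vessels(512)
    bg <- 0.55 + 0.12 * (smooth_surface(64, 64, 0, 1) |> resize_image(c(512, 512)))
    scene <- pmin(pmax(bg, 0), 1)
    dr512 <- resize_image(occupied * 1, c(512, 512), method = "nearest")
    scene[dr512 > 0] <- pmin(scene[dr512 > 0] + 0.10, 1)
    scene[ves$mask] <- 0.22
    baseline_faf <- scene
    scene_f <- scene
    scene_f[ga512 > 0] <- 0.15

    tr <- draw_misalignment(spec$transform_jitter)
    tinv <- invert_transform(tr)
    followup_faf <- warp_image(scene_f, tinv, c(512, 512))
    followup_ga_mask <- as_binary(warp_image(ga512, tinv, c(512, 512),
                                             method = "nearest"))
    baseline_faf <- round(pmin(pmax(
      baseline_faf + 0.02 * stats::rnorm(length(baseline_faf)), 0), 1) * 255) / 255
    followup_faf <- round(pmin(pmax(
      followup_faf + 0.02 * stats::rnorm(length(followup_faf)), 0), 1) * 255) / 255

    case <- structure(list(
      oct = vol, baseline_faf = baseline_faf, followup_faf = followup_faf,
      followup_ga_mask = followup_ga_mask, ga_enface = ga_enface,
      true_transform = tr, keypoints = NULL, layers = layers,
      lesions = lapply(lesions, function(l) l[c("kind", "enface_footprint",
                                                "axial_anchor", "converts")]),
      fiducials = ves$fiducials, spec = spec), class = "phantom_case")
    case$keypoints <- make_keypoints(case, n = 8L)
    case
  })
}

#' @export
print.phantom_case <- function(x, ...) {
  ds <- dim(x$oct)
  kinds <- vapply(x$lesions, `[[`, "", "kind")
  cat(sprintf("<phantom_case: OCT %d x %d x %d, %d lesions (%s), seed %d>\n",
              ds[1], ds[2], ds[3], length(kinds),
              paste(sprintf("%d %s", table(kinds), names(table(kinds))),
                    collapse = ", "),
              x$spec$seed))
  invisible(x)
}

#' Select keypoint correspondences on vessel fiducials
#'
#' Picks `n` fiducial points on the rendered vessel curves in the baseline
#' frame, in general position (no 3 of the points collinear), and maps them
#' through the inverse of the case's true transform to obtain their exact
#' follow-up coordinates. The correspondences therefore reproduce the true
#' transform exactly under homography fitting.
#'
#' @param case A `phantom_case` (or in-progress case with `fiducials` and
#'   `true_transform`).
#' @param n Number of pairs, at least 4.
#' @return A [keypoint_set()] with source = follow-up, destination = baseline.
#' @export
make_keypoints <- function(case, n = 8L) {
  n <- as.integer(n)
  if (n < 4) stop("at least 4 keypoint pairs are required")
  fid <- case$fiducials
  tinv <- invert_transform(case$true_transform)
  general_position <- function(p) {
    idx <- utils::combn(nrow(p), 3)
    for (k in seq_len(ncol(idx))) {
      a <- p[idx[1, k], ]; b <- p[idx[2, k], ]; c <- p[idx[3, k], ]
      area <- abs((b[1] - a[1]) * (c[2] - a[2]) - (c[1] - a[1]) * (b[2] - a[2])) / 2
      if (area < 50) return(FALSE)
    }
    TRUE
  }
  for (attempt in 1:200) {
    pick <- sample(nrow(fid), n)
    dst <- fid[pick, , drop = FALSE]
    src <- transform_points(tinv, dst)
    if (any(src < 0) || any(src > 511)) next
    if (!general_position(dst)) next
    return(keypoint_set(src, dst))
  }
  stop("could not select keypoints in general position")
}
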