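# On-disk representation of a phantom case, matching the pipeline's external
# interfaces: multi-page TIFF for the OCT volume (one page per B-scan), 8-bit
# grayscale PNG for FAF images and masks (masks 0/255), JSON for keypoints and
# transforms (0-based x = column, y = row), CSV for layer boundaries.

case_files <- function(dir) {
  list(oct = file.path(dir, "oct.tiff"),
       baseline_faf = file.path(dir, "baseline_faf.png"),
       followup_faf = file.path(dir, "followup_faf.png"),
       followup_ga_mask = file.path(dir, "followup_ga_mask.png"),
       keypoints = file.path(dir, "keypoints.json"),
       transform = file.path(dir, "transform.json"),
       layers = file.path(dir, "layers.csv"),
       lesions = file.path(dir, "lesions.json"),
       meta = file.path(dir, "case.json"))
}

#' Write a phantom case to a directory
#'
#' The on-disk round trip is lossless for masks, keypoints, transform and
#' layer boundaries; image intensities are stored on the 16-bit (OCT) and
#' 8-bit (FAF) grids they are generated on, so [read_case()] reproduces the
#' case field by field.
#'
#' @param case A `phantom_case`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_case <- function(case, dir) {
  stopifnot(inherits(case, "phantom_case"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- case_files(dir)
  pages <- lapply(seq_len(dim(case$oct)[3]), function(d) case$oct[, , d])
  tiff::writeTIFF(pages, f$oct, bits.per.sample = 16L, compression = "none")
  png::writePNG(case$baseline_faf, f$baseline_faf)
  png::writePNG(case$followup_faf, f$followup_faf)
  png::writePNG(case$followup_ga_mask, f$followup_ga_mask)
  write_keypoints(case$keypoints, f$keypoints)
  write_transform(case$true_transform, f$transform)
  write_layers(case$layers, f$layers)
  les <- lapply(case$lesions, function(l) {
    px <- which(l$enface_footprint > 0, arr.ind = TRUE) - 1L
    list(kind = l$kind, converts = l$converts,
         pixels = unname(apply(px, 1, as.integer, simplify = FALSE)),
         anchors = as.numeric(l$axial_anchor[l$enface_footprint > 0]))
  })
  jsonlite::write_json(les, f$lesions, auto_unbox = TRUE, digits = NA)
  meta <- unclass(case$spec)
  meta$ga_enface_pixels <- unname(apply(
    which(case$ga_enface > 0, arr.ind = TRUE) - 1L, 1, as.integer,
    simplify = FALSE))
  jsonlite::write_json(meta, f$meta, auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a phantom case from a directory
#'
#' @param dir Directory written by [write_case()].
#' @return A `phantom_case`.
#' @export
read_case <- function(dir) {
  f <- case_files(dir)
  for (nm in names(f)) {
    if (!file.exists(f[[nm]])) {
      stop(sprintf("case directory %s is missing file %s", dir,
                   basename(f[[nm]])))
    }
  }
  pages <- tiff::readTIFF(f$oct, all = TRUE)
  vol <- array(0, c(dim(pages[[1]]), length(pages)))
  for (d in seq_along(pages)) vol[, , d] <- pages[[d]]
  meta <- jsonlite::read_json(f$meta)
  spec <- phantom_spec(volume_shape = unlist(meta$volume_shape),
                       n_druse_clusters = meta$n_druse_clusters,
                       n_foci = meta$n_foci, n_sdd = meta$n_sdd,
                       druse_radius_range = unlist(meta$druse_radius_range),
                       focus_radius_range = unlist(meta$focus_radius_range),
                       noise_sigma = meta$noise_sigma,
                       transform_jitter = meta$transform_jitter,
                       conversion_margin = meta$conversion_margin,
                       seed = meta$seed)
  w <- spec$volume_shape[2]; d <- spec$volume_shape[3]
  ga_enface <- matrix(0, w, d)
  for (p in meta$ga_enface_pixels) ga_enface[p[[1]] + 1, p[[2]] + 1] <- 1
  lesions <- lapply(jsonlite::read_json(f$lesions), function(l) {
    fp <- matrix(0, w, d); anc <- matrix(NA_real_, w, d)
    for (i in seq_along(l$pixels)) {
      p <- l$pixels[[i]]
      fp[p[[1]] + 1, p[[2]] + 1] <- 1
      anc[p[[1]] + 1, p[[2]] + 1] <- l$anchors[[i]]
    }
    list(kind = l$kind, enface_footprint = fp, axial_anchor = anc,
         converts = l$converts)
  })
  structure(list(
    oct = vol,
    baseline_faf = read_gray_png(f$baseline_faf),
    followup_faf = read_gray_png(f$followup_faf),
    followup_ga_mask = as_binary(read_gray_png(f$followup_ga_mask)),
    ga_enface = ga_enface,
    true_transform = read_transform(f$transform),
    keypoints = read_keypoints(f$keypoints),
    layers = read_layers(f$layers, height = spec$volume_shape[1]),
    lesions = lesions, fiducials = NULL, spec = spec),
    class = "phantom_case")
}

read_gray_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}

#' Keypoint JSON interchange
#'
#' `{"pairs": [[[xs, ys], [xd, yd]], ...]}` with x = column, y = row, 0-based;
#' source points are in the follow-up FAF frame, destinations in the baseline
#' frame.
#'
#' @param kp A [keypoint_set()].
#' @param path File path.
#' @return `write_keypoints` returns `path` invisibly; `read_keypoints`
#'   returns a [keypoint_set()].
#' @export
write_keypoints <- function(kp, path) {
  stopifnot(inherits(kp, "keypoint_set"))
  pairs <- lapply(seq_len(nrow(kp$src)), function(i) {
    list(as.numeric(kp$src[i, ]), as.numeric(kp$dst[i, ]))
  })
  jsonlite::write_json(list(pairs = pairs), path, digits = I(17))
  invisible(path)
}

#' @rdname write_keypoints
#' @export
read_keypoints <- function(path) {
  obj <- jsonlite::read_json(path)
  src <- t(vapply(obj$pairs, function(p) as.numeric(unlist(p[[1]])), numeric(2)))
  dst <- t(vapply(obj$pairs, function(p) as.numeric(unlist(p[[2]])), numeric(2)))
  keypoint_set(src, dst)
}

#' Planar transform JSON interchange (row-major 3 x 3 matrix)
#'
#' @param t A [planar_transform()].
#' @param path File path.
#' @return `write_transform` returns `path` invisibly; `read_transform`
#'   returns a [planar_transform()].
#' @export
write_transform <- function(t, path) {
  stopifnot(inherits(t, "planar_transform"))
  jsonlite::write_json(
    list(matrix = lapply(1:3, function(i) as.numeric(t$matrix[i, ]))),
    path, digits = I(17))
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  obj <- jsonlite::read_json(path)
  planar_transform(do.call(rbind, lapply(obj$matrix, unlist)))
}

#' Layer boundary CSV interchange
#'
#' Columns `width_index`, `depth_index`, `ilm_row`, `rpe_row`, `cs_row`,
#' all 0-based.
#'
#' @param layers A [layer_boundaries()].
#' @param path File path.
#' @return `write_layers` returns `path` invisibly; `read_layers` returns a
#'   [layer_boundaries()].
#' @export
write_layers <- function(layers, path) {
  stopifnot(inherits(layers, "layer_boundaries"))
  w <- nrow(layers$ilm); d <- ncol(layers$ilm)
  df <- data.frame(width_index = rep(seq_len(w) - 1L, d),
                   depth_index = rep(seq_len(d) - 1L, each = w),
                   ilm_row = as.integer(layers$ilm),
                   rpe_row = as.integer(layers$rpe),
                   cs_row = as.integer(layers$cs))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_layers
#' @param height Axial extent of the volume; defaults to the smallest value
#'   consistent with the stored rows.
#' @export
read_layers <- function(path, height = NULL) {
  df <- utils::read.csv(path)
  w <- max(df$width_index) + 1L; d <- max(df$depth_index) + 1L
  idx <- cbind(df$width_index + 1L, df$depth_index + 1L)
  ilm <- matrix(0L, w, d); rpe <- matrix(0L, w, d); cs <- matrix(0L, w, d)
  ilm[idx] <- df$ilm_row; rpe[idx] <- df$rpe_row; cs[idx] <- df$cs_row
  layer_boundaries(ilm, rpe, cs, height = height %||% (max(df$cs_row) + 1L))
}
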