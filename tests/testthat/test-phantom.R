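test_that("phantom is a deterministic function of its spec", {
  a <- generate_phantom(tiny_spec(seed = 5))
  b <- generate_phantom(tiny_spec(seed = 5))
  expect_identical(a$oct, b$oct)
  expect_identical(a$followup_ga_mask, b$followup_ga_mask)
  expect_identical(a$true_transform$matrix, b$true_transform$matrix)
  expect_identical(a$keypoints$src, b$keypoints$src)
  c <- generate_phantom(tiny_spec(seed = 6))
  expect_false(identical(a$oct, c$oct))
})

test_that("no converting lesions means an empty follow-up annotation", {
  sp <- phantom_spec(volume_shape = c(64, 32, 8), n_druse_clusters = 0,
                     n_foci = 2, n_sdd = 1, focus_radius_range = c(1, 2),
                     druse_radius_range = c(3, 4), seed = 2)
  case <- generate_phantom(sp)
  expect_equal(sum(case$followup_ga_mask), 0)
  expect_equal(sum(case$ga_enface), 0)
})

test_that("with identity alignment and zero margin the annotation equals the druse footprint", {
  case <- generate_phantom(identity_spec(seed = 3, margin = 0L))
  expect_lt(max(abs(case$true_transform$matrix - diag(3))), 1e-12)
  druse <- case$lesions[[which(vapply(case$lesions, `[[`, TRUE, "converts"))]]
  back <- resize_image(case$followup_ga_mask, dim(druse$enface_footprint),
                       method = "nearest")
  expect_identical(back, druse$enface_footprint * 1)
})

test_that("only druse clusters convert, and their dilated footprints avoid other lesions", {
  case <- generate_phantom(small_spec(seed = 4))
  for (les in case$lesions) {
    expect_identical(les$converts, les$kind == "druse_cluster")
    expect_gt(sum(les$enface_footprint), 0)
    if (!les$converts) {
      core <- octga:::erode_disc(les$enface_footprint, 1)
      expect_equal(sum(core & (case$ga_enface > 0)), 0)
    }
  }
})

test_that("layer surfaces are ordered in every A-scan column", {
  case <- generate_phantom(small_spec(seed = 8))
  l <- case$layers
  expect_true(all(l$ilm >= 0))
  expect_true(all(l$ilm < l$rpe))
  expect_true(all(l$rpe < l$cs))
  expect_true(all(l$cs < dim(case$oct)[1]))
  expect_true(all(case$oct >= 0 & case$oct <= 1))
})

test_that("keypoints correspond exactly under the true transform", {
  case <- generate_phantom(small_spec(seed = 9))
  kp <- case$keypoints
  expect_gte(nrow(kp$src), 4)
  mapped <- transform_points(case$true_transform, kp$src)
  expect_lt(max(abs(mapped - kp$dst)), 1e-9)
  # and homography fitting recovers the misalignment from them
  fit <- fit_planar_transform(kp)
  expect_lt(rel_matrix_error(fit$matrix, case$true_transform$matrix), 1e-9)
})

test_that("keypoints on a pure translation differ by exactly that translation", {
  case <- generate_phantom(identity_spec(seed = 10))
  tr <- planar_transform(rbind(c(1, 0, 5), c(0, 1, 3), c(0, 0, 1)))
  wip <- case
  wip$true_transform <- tr
  set.seed(1)
  kp <- make_keypoints(wip, n = 8)
  expect_lt(max(abs(kp$dst - kp$src - matrix(c(5, 3), 8, 2, byrow = TRUE))),
            1e-9)
  # identity case: source equals destination
  set.seed(1)
  kp0 <- make_keypoints(case, n = 4)
  expect_equal(kp0$src, kp0$dst, tolerance = 1e-12)
  # no 3 of the selected points are collinear
  idx <- utils::combn(nrow(kp0$dst), 3)
  for (j in seq_len(ncol(idx))) {
    a <- kp0$dst[idx[1, j], ]; b <- kp0$dst[idx[2, j], ]
    c <- kp0$dst[idx[3, j], ]
    area <- abs((b[1] - a[1]) * (c[2] - a[2]) -
                  (c[1] - a[1]) * (b[2] - a[2])) / 2
    expect_gt(area, 1)
  }
})

test_that("impossible lesion placements fail with a clear error", {
  sp <- phantom_spec(volume_shape = c(64, 24, 8), n_druse_clusters = 12,
                     druse_radius_range = c(8, 10), seed = 1)
  expect_error(generate_phantom(sp), "could not place")
})

test_that("case round-trips through its directory representation", {
  case <- generate_phantom(tiny_spec(seed = 12))
  dir <- withr::local_tempdir()
  write_case(case, dir)
  back <- read_case(dir)
  expect_identical(back$oct, case$oct)
  expect_identical(back$baseline_faf, case$baseline_faf)
  expect_identical(back$followup_faf, case$followup_faf)
  expect_identical(back$followup_ga_mask, case$followup_ga_mask)
  expect_identical(back$ga_enface, case$ga_enface)
  expect_identical(back$keypoints$src, case$keypoints$src)
  expect_identical(back$keypoints$dst, case$keypoints$dst)
  expect_identical(back$true_transform$matrix, case$true_transform$matrix)
  expect_identical(back$layers$ilm, case$layers$ilm)
  expect_identical(back$layers$cs, case$layers$cs)
  expect_equal(length(back$lesions), length(case$lesions))
  for (i in seq_along(case$lesions)) {
    expect_identical(back$lesions[[i]]$enface_footprint,
                     case$lesions[[i]]$enface_footprint)
    expect_identical(back$lesions[[i]]$converts, case$lesions[[i]]$converts)
  }
  # one TIFF page per B-scan
  expect_equal(length(tiff::readTIFF(file.path(dir, "oct.tiff"), all = TRUE)),
               dim(case$oct)[3])
})

test_that("reading a case with a missing file names the file", {
  case <- generate_phantom(tiny_spec(seed = 13))
  dir <- withr::local_tempdir()
  write_case(case, dir)
  file.remove(file.path(dir, "followup_ga_mask.png"))
  expect_error(read_case(dir), "followup_ga_mask.png")
})

test_that("phantom spec validates its invariants", {
  expect_error(phantom_spec(n_druse_clusters = -1))
  expect_error(phantom_spec(druse_radius_range = c(5, 3)))
  expect_error(phantom_spec(volume_shape = c(0, 10, 10)))
  expect_error(phantom_spec(noise_sigma = 2))
})
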