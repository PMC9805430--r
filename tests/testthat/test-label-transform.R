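test_that("homography fitting recovers exact transforms", {
  # identity
  p <- cbind(c(10, 400, 30, 350), c(20, 40, 380, 420))
  t <- fit_planar_transform(keypoint_set(p, p))
  expect_lt(max(abs(t$matrix - diag(3))), 1e-10)

  # pure translation is forced by the correspondences
  t <- fit_planar_transform(keypoint_set(p, cbind(p[, 1] + 5, p[, 2] + 3)))
  expect_lt(max(abs(t$matrix - rbind(c(1, 0, 5), c(0, 1, 3), c(0, 0, 1)))),
            1e-8)

  # random known homographies, noiseless 4-8 point problems
  set.seed(11)
  for (i in 1:50) {
    h <- random_homography()
    src <- random_points(sample(4:8, 1))
    dst <- transform_points(h, src)
    fit <- fit_planar_transform(keypoint_set(src, dst))
    expect_lt(rel_matrix_error(fit$matrix, h$matrix), 1e-6)
  }
})

test_that("degenerate keypoint configurations are rejected", {
  p <- cbind(c(1, 2, 3), c(1, 2, 3))
  expect_error(fit_planar_transform(keypoint_set(p, p)), "at least 4")
  # 3 collinear of 4 leaves the DLT system rank deficient
  p4 <- cbind(c(10, 20, 30, 50), c(10, 20, 30, 200))
  expect_error(fit_planar_transform(keypoint_set(p4, p4)), "degenerate")
})

test_that("warp resamples by inverse mapping and preserves masks", {
  set.seed(3)
  img <- matrix(runif(64 * 64), 64, 64)
  idt <- planar_transform(diag(3))
  expect_equal(warp_image(img, idt), img)

  mask <- matrix(0, 64, 64)
  mask[20:30, 15:25] <- 1
  tr <- planar_transform(rbind(c(1, 0, 5), c(0, 1, 3), c(0, 0, 1)))
  wm <- warp_image(mask, tr, method = "nearest")
  expect_equal(wm[23:33, 20:30], mask[20:30, 15:25])
  expect_equal(sum(wm), sum(mask))  # fully inside the frame

  # warp round trip on random blobs away from borders
  for (i in 1:5) {
    m <- matrix(0, 256, 256)
    cx <- sample(100:156, 1); cy <- sample(100:156, 1)
    m[(cx - 20):(cx + 20), (cy - 15):(cy + 15)] <- 1
    h <- random_homography()
    back <- warp_image(warp_image(m, h, method = "nearest"),
                       invert_transform(h), method = "nearest")
    expect_gte(octga:::dice_coef(back, m), 0.98)
  }
})

test_that("warp of a union equals union of warps for masks", {
  set.seed(4)
  a <- matrix(0, 64, 64); a[5:20, 10:30] <- 1
  b <- matrix(0, 64, 64); b[40:60, 35:55] <- 1
  h <- random_homography()
  wa <- warp_image(a, h, method = "nearest")
  wb <- warp_image(b, h, method = "nearest")
  wu <- warp_image(pmax(a, b), h, method = "nearest")
  expect_equal(wu, pmax(wa, wb))
})

test_that("en-face projection is the mean over height", {
  vol <- array(0.37, c(10, 6, 4))
  expect_equal(project_volume(vol), matrix(0.37, 6, 4))
  vol <- array(0, c(10, 6, 4))
  vol[, 3, 2] <- 1   # one bright A-scan column
  pm <- project_volume(vol)
  expect_equal(pm[3, 2], 1)
  expect_equal(sum(pm), 1)
})

test_that("registration maps annotations into baseline coordinates", {
  p <- cbind(c(10, 400, 30, 350), c(20, 40, 380, 420))
  mask <- matrix(0, 512, 512); mask[100:150, 200:260] <- 1
  expect_equal(register_annotation(mask, keypoint_set(p, p)), mask)
  empty <- matrix(0, 512, 512)
  expect_equal(sum(register_annotation(empty, keypoint_set(p, p))), 0)
})

test_that("extrusion fills exactly the ILM..C-S rows of positive columns", {
  w <- 16L; d <- 6L; h <- 16L
  ilm <- matrix(5L, w, d); rpe <- matrix(7L, w, d); cs <- matrix(9L, w, d)
  layers <- layer_boundaries(ilm, rpe, cs, height = h)
  m <- matrix(0, w, d)
  m[11, 4] <- 1  # en-face pixel (w = 10, d = 3) 0-based
  st <- extrude_label(m, layers, c(h, w, d))
  expect_equal(sum(st), 5)
  expect_equal(which(st[, 11, 4] > 0), 6:10)  # rows 5..9 0-based
  expect_equal(sum(st[, -11, ]), 0)

  expect_equal(sum(extrude_label(matrix(0, w, d), layers, c(h, w, d))), 0)
})

test_that("collapse of an extrusion returns the en-face mask exactly", {
  set.seed(7)
  for (i in 1:20) {
    w <- sample(8:20, 1); d <- sample(4:10, 1); h <- 40L
    layers <- random_layers(w, d, h)
    m <- matrix(rbinom(w * d, 1, 0.3), w, d)
    st <- extrude_label(m, layers, c(h, w, d))
    expect_identical(collapse_label(st), m * 1)
    # no voxel outside the layer band
    for (dd in seq_len(d)) {
      pos <- which(st[, , dd] > 0, arr.ind = TRUE)
      if (nrow(pos) > 0) {
        expect_true(all(pos[, 1] - 1 >= layers$ilm[pos[, 2], dd]))
        expect_true(all(pos[, 1] - 1 <= layers$cs[pos[, 2], dd]))
      }
    }
  }
})

test_that("layer containers enforce ordering and shape", {
  expect_error(layer_boundaries(matrix(5, 4, 4), matrix(4, 4, 4),
                                matrix(9, 4, 4), 16), "ordering")
  expect_error(layer_boundaries(matrix(5, 4, 4), matrix(6, 4, 4),
                                matrix(20, 4, 4), 16), "ordering")
  layers <- layer_boundaries(matrix(2, 4, 4), matrix(6, 4, 4),
                             matrix(9, 4, 4), 16)
  expect_error(extrude_label(matrix(0, 4, 4), layers, c(16, 8, 4)),
               "shape")
  expect_error(extrude_label(matrix(0, 8, 4), layers, c(16, 4, 4)),
               "width x depth")
})

test_that("resize round-trips integer block scaling for masks", {
  set.seed(9)
  m <- matrix(rbinom(32 * 8, 1, 0.4), 32, 8)
  up <- resize_image(m, c(512, 512), method = "nearest")
  down <- resize_image(up, c(32, 8), method = "nearest")
  expect_identical(down, m * 1)
})
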