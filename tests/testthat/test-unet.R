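test_that("network construction obeys its shape and seeding contracts", {
  cfg <- unet_config(depth = 2, base_channels = 8, in_shape = c(64, 64),
                     seed = 21)
  m1 <- build_unet(cfg)
  m2 <- build_unet(cfg)
  expect_identical(m1$params, m2$params)
  x <- matrix(runif(64 * 64), 64, 64)
  pp <- predict(m1, x, channels = TRUE)
  expect_equal(dim(pp), c(64, 64, 2))
  expect_true(all(pp >= 0 & pp <= 1))
  expect_lt(max(abs(pp[, , 1] + pp[, , 2] - 1)), 1e-6)
  # deterministic inference
  expect_identical(predict(m1, x), predict(m1, x))
  expect_error(unet_config(depth = 3, in_shape = c(60, 64)), "divisible")
  expect_error(predict(m1, matrix(0, 32, 64)), "shape")
})

test_that("dice+bce loss matches the printed formula with +1 smoothing", {
  # exact binary match: dice term collapses to 0, bce is at the clamp floor
  truth <- matrix(c(1, 0, 0, 1), 2, 2)
  ls <- dice_bce_loss(truth, truth)
  expect_equal(ls$dice_term, 0)
  expect_lt(ls$bce_term, 1e-6)
  expect_lt(ls$total, 1e-6)

  # empty prediction vs empty truth: smoothing makes the dice term 0
  z <- matrix(0, 4, 4)
  expect_equal(dice_bce_loss(z, z)$dice_term, 0)

  # hand-evaluated case: 2 positives of 4 pixels, uniform prediction 0.9
  pred <- matrix(0.9, 2, 2)
  truth <- matrix(c(1, 1, 0, 0), 2, 2)
  ls <- dice_bce_loss(pred, truth)
  expect_equal(ls$dice_term, 1 - 4.6 / 6.6, tolerance = 1e-12)
  expect_equal(ls$bce_term, -(2 * log(0.9) + 2 * log(0.1)) / 4,
               tolerance = 1e-12)
  expect_equal(ls$total, ls$dice_term + ls$bce_term)
  expect_error(dice_bce_loss(matrix(0, 2, 2), matrix(0, 3, 3)), "mismatch")
})

test_that("loss is permutation equivariant and dice is monotone at true positives", {
  set.seed(31)
  for (i in 1:10) {
    p <- matrix(runif(36), 6, 6)
    t <- matrix(rbinom(36, 1, 0.4), 6, 6)
    perm <- sample(36)
    l1 <- dice_bce_loss(p, t)
    l2 <- dice_bce_loss(matrix(p[perm], 6, 6), matrix(t[perm], 6, 6))
    expect_equal(l1$total, l2$total)
    # raising the prediction at a true positive never increases the dice term
    tp <- which(t == 1)
    if (length(tp) > 0) {
      j <- sample(tp, 1)
      p2 <- p
      p2[j] <- min(1, p[j] + runif(1, 0, 1 - p[j]))
      expect_lte(dice_bce_loss(p2, t)$dice_term, l1$dice_term + 1e-12)
    }
  }
})

test_that("backpropagated gradients match finite differences", {
  set.seed(41)
  m <- tiny_unet(depth = 1, base = 2, in_shape = c(4, 4), seed = 7)
  x <- matrix(runif(16), 4, 4)
  y <- matrix(rbinom(16, 1, 0.5), 4, 4)
  fw <- octga:::forward_unet(m, x, keep = TRUE)
  g <- octga:::backward_unet(m, fw$cache, octga:::dice_bce_grad(fw$prob, y))
  loss_of <- function(mm) {
    dice_bce_loss(octga:::forward_unet(mm, x)$prob, y)$total
  }
  eps <- 1e-6
  paths <- list(
    list(\(mm) mm$params$enc[[1]]$c1$w, \(mm, w) {mm$params$enc[[1]]$c1$w <- w; mm},
         g$enc[[1]]$c1$w),
    list(\(mm) mm$params$bott$c2$w, \(mm, w) {mm$params$bott$c2$w <- w; mm},
         g$bott$c2$w),
    list(\(mm) mm$params$dec[[1]]$up$w, \(mm, w) {mm$params$dec[[1]]$up$w <- w; mm},
         g$dec[[1]]$up$w),
    list(\(mm) mm$params$head$w, \(mm, w) {mm$params$head$w <- w; mm},
         g$head$w))
  for (pth in paths) {
    w <- pth[[1]](m)
    for (j in sample(length(w), 4)) {
      wp <- w; wp[j] <- wp[j] + eps
      wm <- w; wm[j] <- wm[j] - eps
      num <- (loss_of(pth[[2]](m, wp)) - loss_of(pth[[2]](m, wm))) / (2 * eps)
      ana <- pth[[3]][j]
      expect_lt(abs(num - ana) / max(abs(num), abs(ana), 1e-6), 1e-4)
    }
  }
})

test_that("the fused training step reproduces the reference forward/backward", {
  set.seed(51)
  m <- tiny_unet(depth = 2, base = 3, in_shape = c(16, 16), seed = 9)
  x <- matrix(runif(256), 16, 16)
  y <- matrix(rbinom(256, 1, 0.2), 16, 16)
  fw <- octga:::forward_unet(m, x, keep = TRUE)
  ls <- dice_bce_loss(fw$prob, y)
  gr <- octga:::backward_unet(m, fw$cache, octga:::dice_bce_grad(fw$prob, y))
  r <- octga:::cpp_unet_grad(x, y, m$params, 2L, 3L)
  expect_equal(r$loss, ls$total, tolerance = 1e-12)
  expect_equal(r$dice_term, ls$dice_term, tolerance = 1e-12)
  diffs <- octga:::nested_map(function(a, b) max(abs(a - b)), gr, r$grads)
  expect_lt(max(unlist(diffs)), 1e-12)
})

test_that("probability binarization is strictly greater-than", {
  p <- matrix(c(0.5, 0.500001, 0.4999, 0), 2, 2)
  b <- binarize(p)
  expect_equal(b, matrix(c(0, 1, 0, 0), 2, 2))
  expect_equal(sum(binarize(matrix(0, 4, 4))), 0)
  expect_error(binarize(p, threshold = 0))
})

test_that("training is seeded, records history, and rejects empty data", {
  m <- tiny_unet(depth = 2, base = 2, in_shape = c(16, 16), seed = 3,
                 epochs = 1, batch_size = 2)
  expect_error(train_unet(m, list()), "empty")
  set.seed(61)
  samples <- lapply(1:3, function(i) {
    list(x = matrix(runif(256), 16, 16), y = matrix(rbinom(256, 1, 0.3), 16, 16))
  })
  f1 <- train_unet(m, samples, epochs = 1)
  expect_equal(nrow(f1$history), 1)
  expect_true(is.finite(f1$history$mean_loss))
  f2 <- train_unet(m, samples, epochs = 1)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("the trainer can memorize a handful of phantom B-scans", {
  sp <- phantom_spec(volume_shape = c(64L, 64L, 8L), n_druse_clusters = 1L,
                     n_foci = 1L, n_sdd = 0L,
                     druse_radius_range = c(11, 13),
                     focus_radius_range = c(2, 3), noise_sigma = 0.05,
                     transform_jitter = list(translate = 0, rotate = 0,
                                             projective = 0),
                     conversion_margin = 1L, seed = 17)
  pr <- prepare_case(generate_phantom(sp), "m")
  pos <- which(apply(pr$truth_stack, 3, sum) > 0)
  samples <- lapply(pos[1:4], function(d) list(x = pr$oct[, , d],
                                               y = pr$truth_stack[, , d]))
  fits <- list()
  for (seed in c(1, 2, 3)) {
    m <- build_unet(unet_config(depth = 2, base_channels = 16,
                                in_shape = c(64, 64), seed = seed,
                                epochs = 50, batch_size = 1,
                                learning_rate = 2e-3),
                    head_bias = c(0, 2))
    fits[[seed]] <- train_unet(m, samples)
    expect_lt(utils::tail(fits[[seed]]$history$mean_loss, 1), 0.1)
  }

  # the memorized model concentrates probability mass inside the truth
  model <- fits[[1]]$model
  case <- generate_phantom(sp)
  druse <- case$lesions[[1]]
  d0 <- which(colSums(druse$enface_footprint) > 0 &
                seq_len(8) %in% pos[1:4])[1]
  p <- predict(model, pr$oct[, , d0])
  truth <- pr$truth_stack[, , d0]
  expect_gt(mean(p[truth > 0]), mean(p[truth == 0]))

  # and its deconvnet saliency overlaps the druse footprint columns
  best <- 0
  for (d in intersect(which(colSums(druse$enface_footprint) > 0), pos[1:4])) {
    sal <- saliency_image(reconstruct_stack(model, pr$oct[, , d]))
    best <- max(best, octga:::dice_coef(
      (colSums(sal > 0.5) > 0) * 1, (druse$enface_footprint[, d] > 0) * 1))
  }
  expect_gte(best, 0.3)
})

test_that("checkpoints round-trip through disk", {
  m <- tiny_unet(seed = 5)
  dir <- withr::local_tempdir()
  save_unet(m, file.path(dir, "model"))
  back <- load_unet(file.path(dir, "model"))
  expect_identical(back$params, m$params)
  expect_true(file.exists(file.path(dir, "model.json")))
  expect_error(load_unet(file.path(dir, "nope")), "nope")
})
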