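test_that("en-face aggregation averages columns and resizes", {
  maps <- lapply(1:4, function(i) matrix(0.37, 16, 8))
  agg <- aggregate_enface(maps, 64)
  expect_equal(dim(agg), c(64, 64))
  expect_equal(max(abs(agg - 0.37)), 0)

  maps <- lapply(1:4, function(i) matrix(0, 16, 8))
  maps[[2]] <- matrix(1, 16, 8)
  agg <- aggregate_enface(maps, 64)
  # depth slice 2 of 4: its center column carries the full value, the other
  # slices' centers none (bilinear blending in between)
  expect_gte(max(agg), 0.95)
  expect_lte(max(agg), 1)
  expect_true(which.max(colMeans(agg)) %in% 20:28)
  expect_true(all(agg[, c(1:8, 41:64)] == 0))
  expect_error(aggregate_enface(list()), "no probability")
})

test_that("aggregating the extruded truth recovers the registered annotation", {
  case <- generate_phantom(small_spec(seed = 14))
  pr <- prepare_case(case, "agg")
  d <- dim(pr$oct)[3]
  probs <- lapply(seq_len(d), function(i) pr$truth_stack[, , i] * 1)
  agg <- aggregate_enface(probs)
  # column means are diluted by the non-retina rows; renormalize before the
  # half-maximum threshold
  mask <- (agg / max(agg) > 0.5) * 1
  expect_gte(octga:::dice_coef(mask, pr$truth_enface), 0.95)
})

test_that("otsu thresholds maximize between-class variance", {
  v <- c(rep(0.1, 50), rep(0.9, 50))
  t2 <- otsu_thresholds(matrix(v, 10, 10), 2)
  expect_gt(t2, 0.1); expect_lt(t2, 0.9)

  v3 <- c(rep(0.1, 40), rep(0.5, 30), rep(0.9, 30))
  t3 <- otsu_thresholds(matrix(v3, 10, 10), 3)
  expect_equal(length(t3), 2)
  expect_gt(t3[1], 0.1); expect_lt(t3[1], 0.5)
  expect_gt(t3[2], 0.5); expect_lt(t3[2], 0.9)
  expect_lt(t3[1], t3[2])

  expect_error(otsu_thresholds(matrix(0.5, 4, 4), 2), "constant")
  expect_error(otsu_thresholds(matrix(runif(16), 4, 4), 4), "2 or 3")
})

test_that("otsu agrees with an exhaustive histogram search", {
  # independent oracle: minimize the within-class weighted variance over all
  # cuts of the same 256-bin histogram
  oracle_var <- function(v, cuts) {
    nb <- 256L
    edges <- seq(0, 1, length.out = nb + 1)
    bin <- pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1), nb)
    mids <- (edges[-1] + edges[-(nb + 1)]) / 2
    bounds <- c(0, cuts, nb)
    tot <- 0
    for (ci in seq_len(length(bounds) - 1)) {
      sel <- bin > bounds[ci] & bin <= bounds[ci + 1]
      if (any(sel)) {
        x <- mids[bin[sel]]
        tot <- tot + sum((x - mean(x))^2)
      }
    }
    tot / length(v)
  }
  set.seed(15)
  for (rep in 1:6) {
    v <- c(runif(120, 0, 0.4), runif(80, 0.5, 1))
    m <- matrix(v, 20, 10)
    edges <- seq(0, 1, length.out = 257)
    # 2-class: implementation's cut must attain the oracle minimum
    t2 <- otsu_thresholds(m, 2)
    k2 <- which.min(abs(edges - t2)) - 1L
    best2 <- min(vapply(1:255, function(k) oracle_var(v, k), numeric(1)))
    expect_equal(oracle_var(v, k2), best2, tolerance = 1e-12)
    # 3-class
    t3 <- otsu_thresholds(m, 3)
    k3 <- vapply(t3, function(t) which.min(abs(edges - t)) - 1L, integer(1))
    best3 <- Inf
    for (k1 in 1:254) {
      vals <- vapply((k1 + 1):255, function(k2_) oracle_var(v, c(k1, k2_)),
                     numeric(1))
      best3 <- min(best3, min(vals))
    }
    expect_equal(oracle_var(v, k3), best3, tolerance = 1e-12)
  }
})

test_that("binarization mode selection maximizes dice against truth", {
  set.seed(16)
  truth <- matrix(0, 64, 64); truth[10:30, 10:30] <- 1
  sel <- select_binarization(truth + 0, truth)
  expect_equal(sel$mode, "otsu2")  # tie goes to the 2-class variant
  expect_equal(sel$dice, 1)

  # noisy map: the chosen candidate is never worse than either single one
  map <- matrix(runif(64 * 64, 0, 0.4), 64, 64)
  map[10:30, 10:30] <- map[10:30, 10:30] + 0.5
  sel <- select_binarization(map, truth)
  t2 <- otsu_thresholds(map, 2)
  t3 <- otsu_thresholds(map, 3)[2]
  d2 <- octga:::dice_coef((map > t2) * 1, truth)
  d3 <- octga:::dice_coef((map > t3) * 1, truth)
  expect_gte(sel$dice, max(d2, d3))

  # empty truth: no-smoothing dice is 0 for any nonempty candidate (and
  # would be 1 only for an empty one); the tie resolves to 2-class
  noise <- matrix(runif(64 * 64), 64, 64)
  empty <- matrix(0, 64, 64)
  sel <- select_binarization(noise, empty)
  expect_equal(sel$dice, 0)
  expect_equal(sel$mode, "otsu2")
  # the empty-vs-empty convention itself
  expect_equal(octga:::dice_coef(empty, empty), 1)
})

test_that("confusion counts match a nested-loop oracle", {
  set.seed(17)
  for (rep in 1:20) {
    p <- matrix(rbinom(100, 1, 0.4), 10, 10)
    t <- matrix(rbinom(100, 1, 0.4), 10, 10)
    cc <- confusion_counts(p, t)
    tp <- fp <- tn <- fn <- 0
    for (i in 1:10) for (j in 1:10) {
      if (p[i, j] == 1 && t[i, j] == 1) tp <- tp + 1
      else if (p[i, j] == 1) fp <- fp + 1
      else if (t[i, j] == 1) fn <- fn + 1
      else tn <- tn + 1
    }
    expect_equal(c(cc$tp, cc$fp, cc$tn, cc$fn), c(tp, fp, tn, fn))
    expect_equal(cc$total, 100)
  }
  t <- matrix(rbinom(100, 1, 0.5), 10, 10)
  cc <- confusion_counts(1 - t, t)
  expect_equal(cc$tp + cc$tn, 0)
  expect_error(confusion_counts(matrix(0, 2, 2), matrix(0, 3, 3)), "mismatch")
})

test_that("metrics follow the confusion-matrix formulas with NA for 0/0", {
  cc <- structure(list(tp = 3, fp = 1, tn = 5, fn = 1, total = 10),
                  class = "confusion_counts")
  m <- compute_metrics(cc)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$specificity, 5 / 6)
  expect_equal(m$overlap, 0.6)
  expect_equal(m$tp_fraction, 0.3)
  # algebraic identity
  expect_equal(m$accuracy, 1 - (cc$fp + cc$fn) / cc$total)

  perfect <- confusion_counts(matrix(c(1, 0), 2, 2), matrix(c(1, 0), 2, 2))
  mp <- compute_metrics(perfect)
  expect_equal(c(mp$accuracy, mp$sensitivity, mp$specificity, mp$overlap),
               rep(1, 4))

  none <- confusion_counts(matrix(0, 2, 2), matrix(0, 2, 2))
  mn <- compute_metrics(none)
  expect_true(is.na(mn$sensitivity))
  expect_true(is.na(mn$overlap))
  expect_equal(mn$accuracy, 1)
})

test_that("cross-validation partitions cases evenly and averages case metrics", {
  preps <- lapply(1:4, function(i) {
    prepare_case(generate_phantom(tiny_spec(seed = 20 + i)), paste0("c", i))
  })
  cfg <- unet_config(depth = 2, base_channels = 2, in_shape = c(64, 32),
                     epochs = 1, batch_size = 2, seed = 1)
  cv <- crossvalidate(preps, k = 2, seed = 3, net_cfg = cfg,
                      bscans_per_case = 2)
  expect_s3_class(cv, "cv_result")
  sizes <- vapply(cv$folds, function(f) length(f$case_ids), integer(1))
  expect_lte(max(sizes) - min(sizes), 1)
  expect_setequal(cv$per_case$case_id, paste0("c", 1:4))
  # combined equals the mean over per-case rows recomputed independently
  expect_equal(unname(cv$combined["accuracy"]),
               mean(cv$per_case$accuracy, na.rm = TRUE))
  expect_equal(unname(cv$combined["overlap"]),
               mean(cv$per_case$overlap, na.rm = TRUE))
  expect_error(crossvalidate(preps, k = 9, seed = 1, net_cfg = cfg),
               "more folds")
  # metrics CSV layout
  path <- withr::local_tempfile(fileext = ".csv")
  write_metrics_csv(cv, path)
  df <- utils::read.csv(path)
  expect_equal(names(df), c("fold", "accuracy", "sensitivity", "specificity",
                            "overlap"))
  expect_equal(nrow(df), 3)
  expect_equal(df$fold[3], "combined")
})
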