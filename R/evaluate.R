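# Evaluation of the segmentation pipeline: depth-wise aggregation of
# per-B-scan probability maps into a 512 x 512 en-face projection,
# binarization via the better of 2- and 3-class Otsu thresholds (selected by
# Dice against the registered ground truth), confusion-matrix metrics, and
# k-fold cross-validation over cases.

#' Aggregate per-B-scan probabilities into an en-face map
#'
#' Column-averages each B-scan's probability map along the height axis (one
#' width-length profile per B-scan), stacks the profiles over depth into a
#' (width x depth) map, and bilinearly resizes to the square 512 x 512
#' en-face frame.
#'
#' @param prob_bscans List of (height x width) probability matrices, ordered
#'   by depth.
#' @param out_size En-face frame size (default 512).
#' @return (out_size x out_size) matrix in `[0, 1]`.
#' @export
aggregate_enface <- function(prob_bscans, out_size = 512L) {
  if (length(prob_bscans) == 0) stop("no probability maps to aggregate")
  d0 <- dim(prob_bscans[[1]])
  for (p in prob_bscans) {
    if (!all(dim(p) == d0)) stop("probability maps must share one shape")
  }
  wd <- vapply(prob_bscans, colMeans, numeric(d0[2]))
  resize_image(wd, c(out_size, out_size), method = "bilinear")
}

#' Multi-class Otsu thresholds
#'
#' Thresholds maximizing the between-class variance of a 256-bin histogram on
#' `[0, 1]`; the 3-class variant searches all bin-edge pairs exhaustively.
#'
#' @param map Numeric matrix with values in `[0, 1]`, not constant.
#' @param n_classes 2 or 3.
#' @return Numeric vector of 1 (`n_classes = 2`) or 2 strictly increasing
#'   (`n_classes = 3`) thresholds.
#' @export
otsu_thresholds <- function(map, n_classes = 2L) {
  v <- as.numeric(map)
  if (any(v < 0 | v > 1)) stop("Otsu thresholding expects values in [0, 1]")
  if (diff(range(v)) < .Machine$double.eps) {
    stop("constant map: Otsu thresholding is degenerate")
  }
  if (!n_classes %in% c(2L, 3L)) stop("n_classes must be 2 or 3")
  nb <- 256L
  edges <- seq(0, 1, length.out = nb + 1)
  bin <- pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1L), nb)
  cnt <- tabulate(bin, nbins = nb)
  mids <- (edges[-1] + edges[-(nb + 1)]) / 2
  W <- cumsum(cnt)
  M <- cumsum(cnt * mids)
  n <- W[nb]; mu <- M[nb] / n
  csum <- function(a, b) {  # class weight and sum over bins (a, b]
    w <- W[b] - if (a >= 1) W[a] else 0
    m <- M[b] - if (a >= 1) M[a] else 0
    c(w, m)
  }
  between_var <- function(cuts) {
    bounds <- c(0L, cuts, nb)
    s <- 0
    for (ci in seq_len(length(bounds) - 1)) {
      cm <- csum(bounds[ci], bounds[ci + 1])
      if (cm[1] > 0) s <- s + cm[1] * (cm[2] / cm[1] - mu)^2
    }
    s / n
  }
  if (n_classes == 2L) {
    w0 <- W[-nb]; m0 <- M[-nb]
    w1 <- n - w0; m1 <- M[nb] - m0
    sb <- ifelse(w0 > 0 & w1 > 0,
                 w0 * (m0 / w0 - mu)^2 + w1 * (m1 / w1 - mu)^2, -Inf) / n
    k <- which.max(sb)
    return(edges[k + 1])
  }
  best <- -Inf; bk <- c(1L, 2L)
  for (k1 in 1:(nb - 2)) {
    c0 <- csum(0L, k1)
    if (c0[1] == 0) next
    t0 <- c0[1] * (c0[2] / c0[1] - mu)^2
    w1 <- W[(k1 + 1):(nb - 1)] - W[k1]
    m1 <- M[(k1 + 1):(nb - 1)] - M[k1]
    w2 <- n - W[(k1 + 1):(nb - 1)]
    m2 <- M[nb] - M[(k1 + 1):(nb - 1)]
    sb <- t0 + ifelse(w1 > 0, w1 * (m1 / w1 - mu)^2, NA) +
      ifelse(w2 > 0, w2 * (m2 / w2 - mu)^2, NA)
    sb[is.na(sb)] <- -Inf
    j <- which.max(sb)
    if (sb[j] > best) {
      best <- sb[j]; bk <- c(k1, k1 + j)
    }
  }
  edges[bk + 1]
}

#' Choose the better Otsu binarization against ground truth
#'
#' Candidate masks are `map > t` for the 2-class threshold and
#' `map > upper t` for the 3-class pair; the candidate with the higher Dice
#' score against the truth wins (ties go to 2-class). Dice here uses no
#' smoothing and defines empty-vs-empty as 1.
#'
#' @param map En-face probability matrix.
#' @param truth Binary ground-truth matrix of the same shape.
#' @return List with `mask` (binary matrix), `mode` (`"otsu2"`/`"otsu3"`),
#'   `threshold` and `dice`.
#' @export
select_binarization <- function(map, truth) {
  if (!all(dim(map) == dim(truth))) stop("map/truth shape mismatch")
  t2 <- otsu_thresholds(map, 2L)
  t3 <- otsu_thresholds(map, 3L)[2]
  m2 <- (map > t2) * 1
  m3 <- (map > t3) * 1
  d2 <- dice_coef(m2, truth)
  d3 <- dice_coef(m3, truth)
  if (d2 >= d3) list(mask = m2, mode = "otsu2", threshold = t2, dice = d2)
  else list(mask = m3, mode = "otsu3", threshold = t3, dice = d3)
}

#' Pixelwise confusion counts
#'
#' @param pred,truth Binary matrices of equal shape.
#' @return Object of class `confusion_counts` with `tp`, `fp`, `tn`, `fn`,
#'   `total`.
#' @export
confusion_counts <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth))) stop("prediction/truth shape mismatch")
  p <- pred > 0; t <- truth > 0
  cc <- list(tp = sum(p & t), fp = sum(p & !t), tn = sum(!p & !t),
             fn = sum(!p & t))
  cc$total <- cc$tp + cc$fp + cc$tn + cc$fn
  structure(cc, class = "confusion_counts")
}

#' Segmentation metrics from confusion counts
#'
#' `accuracy = (TP + TN) / total`, `sensitivity = TP / (TP + FN)`,
#' `specificity = TN / (TN + FP)`, and `overlap` in its Jaccard reading
#' `TP / (TP + FP + FN)`; the raw fraction `TP / total` is also reported as
#' `tp_fraction`. A metric whose denominator is zero is reported as `NA`,
#' never coerced to 0 or 1.
#'
#' @param cc A [confusion_counts()].
#' @return Object of class `metrics_report`.
#' @export
compute_metrics <- function(cc) {
  stopifnot(inherits(cc, "confusion_counts"))
  if (cc$total <= 0) stop("empty confusion matrix")
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  structure(list(
    accuracy = safe(cc$tp + cc$tn, cc$total),
    sensitivity = safe(cc$tp, cc$tp + cc$fn),
    specificity = safe(cc$tn, cc$tn + cc$fp),
    overlap = safe(cc$tp, cc$tp + cc$fp + cc$fn),
    tp_fraction = safe(cc$tp, cc$total)), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "accuracy %.3f  sensitivity %.3f  specificity %.3f  overlap %.3f\n",
    x$accuracy, x$sensitivity, x$specificity, x$overlap))
  invisible(x)
}

metrics_row <- function(m) {
  vapply(c("accuracy", "sensitivity", "specificity", "overlap",
           "tp_fraction"), function(nm) m[[nm]], numeric(1))
}

#' Prepare a phantom case for training and evaluation
#'
#' Registers the follow-up GA annotation into the baseline en-face frame via
#' the case's keypoints, resamples it to the volume's lateral grid and
#' extrudes it between the ILM and C-S boundaries into per-B-scan ground
#' truth.
#'
#' @param case A `phantom_case`.
#' @param id Case identifier.
#' @return List with `id`, `oct`, `truth_stack` (height x width x depth),
#'   `truth_enface` (512 x 512 registered baseline-frame truth) and the
#'   originating `case`.
#' @export
prepare_case <- function(case, id = "case") {
  stopifnot(inherits(case, "phantom_case"))
  ds <- dim(case$oct)
  truth512 <- register_annotation(case$followup_ga_mask, case$keypoints,
                                  c(512L, 512L))
  enface_wd <- resize_image(truth512, ds[2:3], method = "nearest")
  stack <- extrude_label(enface_wd, case$layers, ds)
  list(id = id, oct = case$oct, truth_stack = stack, truth_enface = truth512,
       case = case)
}

# Seeded choice of training B-scans for one case: half from slices carrying
# positive labels, half from the rest (all slices when n is NULL or >= depth).
select_bscans <- function(prep, n) {
  d <- dim(prep$oct)[3]
  if (is.null(n) || n >= d) return(seq_len(d))
  pos <- which(apply(prep$truth_stack, 3, sum) > 0)
  neg <- setdiff(seq_len(d), pos)
  npos <- min(length(pos), ceiling(n / 2))
  take <- c(if (npos > 0) sample(pos, npos),
            sample(neg, min(length(neg), n - npos)))
  if (length(take) < n && length(pos) > npos) {
    take <- c(take, sample(setdiff(pos, take), n - length(take)))
  }
  sort(take)
}

# resample a B-scan (and its mask) to the network's input grid when the
# configured shape differs from the native B-scan shape
net_input <- function(bscan, in_shape) {
  if (all(dim(bscan) == in_shape)) bscan
  else resize_image(bscan, in_shape, method = "bilinear")
}

net_mask <- function(mask, in_shape) {
  if (all(dim(mask) == in_shape)) mask
  else resize_image(mask, in_shape, method = "nearest")
}

evaluate_case <- function(model, prep) {
  d <- dim(prep$oct)[3]
  probs <- lapply(seq_len(d), function(di) {
    predict(model, net_input(prep$oct[, , di], model$cfg$in_shape))
  })
  agg <- aggregate_enface(probs, nrow(prep$truth_enface))
  sel <- select_binarization(agg, prep$truth_enface)
  met <- compute_metrics(confusion_counts(sel$mask, prep$truth_enface))
  list(metrics = met, mode = sel$mode, dice = sel$dice, enface = agg,
       mask = sel$mask)
}

#' k-fold cross-validation of the full pipeline
#'
#' Partitions cases into k near-equal folds (seeded), trains a fresh network
#' on each k-1 fold split, and pushes every held-out case through the full
#' pipeline: per-B-scan prediction, en-face aggregation, Otsu binarization
#' selected by Dice against the registered truth, and confusion-matrix
#' metrics. Fold reports average their held-out cases; the primary combined
#' report is the mean over all cases, with the mean over fold means also
#' reported.
#'
#' @param preps List of [prepare_case()] results.
#' @param k Number of folds (default 8); must not exceed the case count.
#' @param seed Seed controlling the partition and per-fold training.
#' @param net_cfg A [unet_config()] template; its seed is re-derived per fold.
#' @param bscans_per_case Training B-scans drawn per case (NULL = all).
#' @param verbose Report per-fold progress.
#' @return Object of class `cv_result`: `folds` (per-fold ids, case ids,
#'   reports, trained models), `per_case` data frame, `combined` (mean over
#'   cases), `combined_by_fold`.
#' @export
crossvalidate <- function(preps, k = 8L, seed = 1L, net_cfg,
                          bscans_per_case = NULL, verbose = FALSE) {
  n <- length(preps)
  if (k > n) stop("more folds than cases")
  with_seed(seed, {
    fold_of <- rep(seq_len(k), length.out = n)[sample(n)]
    folds <- vector("list", k)
    rows <- list()
    for (f in seq_len(k)) {
      hold <- which(fold_of == f)
      tr <- which(fold_of != f)
      samples <- list()
      for (ci in tr) {
        sel <- select_bscans(preps[[ci]], bscans_per_case)
        for (di in sel) {
          samples[[length(samples) + 1]] <-
            list(x = net_input(preps[[ci]]$oct[, , di], net_cfg$in_shape),
                 y = net_mask(preps[[ci]]$truth_stack[, , di],
                              net_cfg$in_shape))
        }
      }
      cfg_f <- net_cfg
      cfg_f$seed <- as.integer(seed * 1000L + f)
      fit <- train_unet(build_unet(cfg_f), samples, verbose = FALSE)
      fold_rows <- list()
      for (ci in hold) {
        ev <- evaluate_case(fit$model, preps[[ci]])
        fold_rows[[length(fold_rows) + 1]] <-
          c(list(fold = f, case_id = preps[[ci]]$id, mode = ev$mode),
            as.list(metrics_row(ev$metrics)))
      }
      rows <- c(rows, fold_rows)
      fr <- do.call(rbind, lapply(fold_rows, function(r) {
        unlist(r[c("accuracy", "sensitivity", "specificity", "overlap",
                   "tp_fraction")])
      }))
      folds[[f]] <- list(fold_id = f,
                         case_ids = vapply(preps[hold], `[[`, "", "id"),
                         report = colMeans(fr, na.rm = TRUE),
                         model = fit$model, history = fit$history)
      if (verbose) {
        message(sprintf("fold %d/%d: accuracy %.3f overlap %.3f", f, k,
                        folds[[f]]$report["accuracy"],
                        folds[[f]]$report["overlap"]))
      }
    }
    per_case <- do.call(rbind, lapply(rows, function(r) {
      data.frame(fold = r$fold, case_id = r$case_id, mode = r$mode,
                 accuracy = r$accuracy, sensitivity = r$sensitivity,
                 specificity = r$specificity, overlap = r$overlap,
                 tp_fraction = r$tp_fraction)
    }))
    met_cols <- c("accuracy", "sensitivity", "specificity", "overlap",
                  "tp_fraction")
    combined <- colMeans(per_case[met_cols], na.rm = TRUE)
    by_fold <- colMeans(do.call(rbind, lapply(folds, `[[`, "report")),
                        na.rm = TRUE)
    structure(list(folds = folds, per_case = per_case, combined = combined,
                   combined_by_fold = by_fold, k = k, seed = seed),
              class = "cv_result")
  })
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result: %d folds, %d cases>\n", x$k, nrow(x$per_case)))
  for (f in x$folds) {
    cat(sprintf("  fold %d: accuracy %.3f sensitivity %.3f specificity %.3f overlap %.3f\n",
                f$fold_id, f$report["accuracy"], f$report["sensitivity"],
                f$report["specificity"], f$report["overlap"]))
  }
  cat(sprintf("  combined (mean over cases): accuracy %.3f sensitivity %.3f specificity %.3f overlap %.3f\n",
              x$combined["accuracy"], x$combined["sensitivity"],
              x$combined["specificity"], x$combined["overlap"]))
  invisible(x)
}

#' Write cross-validation metrics in the per-fold CSV layout
#'
#' One row per fold plus a `combined` row (mean over held-out cases), columns
#' fold, accuracy, sensitivity, specificity, overlap.
#'
#' @param cv A [crossvalidate()] result.
#' @param path Output CSV path.
#' @return `path` invisibly.
#' @export
write_metrics_csv <- function(cv, path) {
  stopifnot(inherits(cv, "cv_result"))
  rows <- do.call(rbind, lapply(cv$folds, function(f) {
    data.frame(fold = as.character(f$fold_id - 1L),
               accuracy = f$report["accuracy"],
               sensitivity = f$report["sensitivity"],
               specificity = f$report["specificity"],
               overlap = f$report["overlap"])
  }))
  rows <- rbind(rows, data.frame(fold = "combined",
                                 accuracy = cv$combined["accuracy"],
                                 sensitivity = cv$combined["sensitivity"],
                                 specificity = cv$combined["specificity"],
                                 overlap = cv$combined["overlap"]))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
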