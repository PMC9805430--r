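# Square-filter U-Net for per-B-scan segmentation of future geographic
# atrophy, trained with the combined soft-Dice + binary cross-entropy loss.
# Forward/backward passes are composed from the package's GEMM-based
# convolution kernels; feature maps are (height x width x channels) arrays.

#' Network configuration
#'
#' @param depth Number of 2x2 max-pooling levels.
#' @param base_channels Channels of the first encoder block; doubled at each
#'   deeper level.
#' @param kernel_size Square convolution extent (odd).
#' @param in_shape Input (height, width); both must be divisible by
#'   `2^depth`.
#' @param learning_rate Adam step size (the training default is `1e-4`).
#' @param epochs Training epochs.
#' @param batch_size Mini-batch size (gradients averaged per batch).
#' @param precision Arithmetic of the fused training step: `"single"`
#'   (default, the usual choice for network training) or `"double"`.
#' @param seed Seed for weight initialization and epoch shuffling.
#' @return An object of class `unet_config`.
#' @export
unet_config <- function(depth = 4L, base_channels = 16L, kernel_size = 3L,
                        in_shape = c(256L, 128L), learning_rate = 1e-4,
                        epochs = 50L, batch_size = 8L,
                        precision = c("single", "double"), seed = 1L) {
  precision <- match.arg(precision)
  depth <- as.integer(depth); in_shape <- as.integer(in_shape)
  if (kernel_size %% 2 != 1) stop("kernel_size must be odd (square 'same' filters)")
  if (any(in_shape %% 2^depth != 0)) {
    stop(sprintf("in_shape (%d, %d) must be divisible by 2^depth = %d",
                 in_shape[1], in_shape[2], 2^depth))
  }
  structure(list(depth = depth, base_channels = as.integer(base_channels),
                 kernel_size = as.integer(kernel_size), in_shape = in_shape,
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), precision = precision,
                 seed = as.integer(seed)),
            class = "unet_config")
}

he_init <- function(nin, nout, fan) {
  matrix(stats::rnorm(nin * nout, sd = sqrt(2 / fan)), nin, nout)
}

#' Build an untrained U-Net
#'
#' Encoder-decoder with `depth` levels: two square convolutions + rectifier
#' per block, 2x2 max pooling, channel doubling per level, 2x2 stride-2
#' up-convolutions, skip connections by channel concatenation, and a final
#' 1x1 convolution to two classes followed by a softmax. Weights are
#' He-initialized deterministically from the config seed.
#'
#' @param cfg A [unet_config()].
#' @param head_bias Optional length-2 initial bias of the class head
#'   (positive, negative). Setting a positive negative-class bias encodes a
#'   background prior, which stabilizes early training under the strong class
#'   imbalance typical of lesion segmentation; `NULL` initializes at zero.
#' @return An object of class `octga_unet`.
#' @export
build_unet <- function(cfg, head_bias = NULL) {
  stopifnot(inherits(cfg, "unet_config"))
  k <- cfg$kernel_size; base <- cfg$base_channels; dp <- cfg$depth
  with_seed(cfg$seed, {
    conv_pair <- function(cin, cmid, cout) {
      list(c1 = list(w = he_init(k * k * cin, cmid, k * k * cin),
                     b = numeric(cmid)),
           c2 = list(w = he_init(k * k * cmid, cout, k * k * cmid),
                     b = numeric(cout)))
    }
    enc <- lapply(seq_len(dp), function(i) {
      cin <- if (i == 1) 1L else base * 2^(i - 2)
      conv_pair(cin, base * 2^(i - 1), base * 2^(i - 1))
    })
    bott <- conv_pair(base * 2^(dp - 1), base * 2^dp, base * 2^dp)
    dec <- lapply(seq_len(dp), function(i) {
      co <- base * 2^(i - 1)
      c(list(up = list(w = he_init(4 * 2 * co, co, 4 * 2 * co),
                       b = numeric(co))),
        conv_pair(2L * co, co, co))
    })
    head <- list(w = he_init(base, 2, base),
                 b = as.numeric(head_bias %||% c(0, 0)))
    structure(list(cfg = cfg,
                   params = list(enc = enc, bott = bott, dec = dec,
                                 head = head)),
              class = "octga_unet")
  })
}

#' @export
print.octga_unet <- function(x, ...) {
  cfg <- x$cfg
  np <- sum(unlist(rapply(x$params, length, how = "unlist")))
  cat(sprintf(paste0("<octga_unet: depth %d, base %d channels, %dx%d filters, ",
                     "input %d x %d, %d parameters%s>\n"),
              cfg$depth, cfg$base_channels, cfg$kernel_size, cfg$kernel_size,
              cfg$in_shape[1], cfg$in_shape[2], np,
              if (isTRUE(x$trained)) ", trained" else ""))
  invisible(x)
}

as_feature_cube <- function(x) {
  if (length(dim(x)) == 2) array(x, c(dim(x), 1L)) else x
}

#' Normalize a B-scan to the unit intensity interval
#'
#' Per-scan min-max normalization applied to every network input.
#'
#' @param x Numeric matrix.
#' @return Matrix with values in `[0, 1]`.
#' @export
normalize_bscan <- function(x) {
  rng <- range(x)
  if (rng[2] > rng[1]) (x - rng[1]) / (rng[2] - rng[1]) else x * 0
}

block_fwd <- function(x, prm, k, ws = FALSE) {
  z1 <- cpp_conv2d_fwd(x, prm$c1$w, prm$c1$b, k)
  a1 <- pmax(z1, 0)
  z2 <- cpp_conv2d_fwd(a1, prm$c2$w, prm$c2$b, k)
  list(x = x, z1 = z1, a1 = a1, z2 = z2, out = pmax(z2, 0))
}

block_bwd <- function(dout, cb, prm, k) {
  dz2 <- dout * (cb$z2 > 0)
  r2 <- cpp_conv2d_bwd(cb$a1, prm$c2$w, dz2, k)
  dz1 <- r2$dx * (cb$z1 > 0)
  r1 <- cpp_conv2d_bwd(cb$x, prm$c1$w, dz1, k)
  list(dx = r1$dx,
       g = list(c1 = list(w = r1$dw, b = r1$db),
                c2 = list(w = r2$dw, b = r2$db)))
}

# Full forward pass. Returns the positive-class probability map and, if
# keep = TRUE, every intermediate needed for backprop / deconvnet inversion.
forward_unet <- function(model, bscan, keep = FALSE) {
  cfg <- model$cfg; k <- cfg$kernel_size; dp <- cfg$depth
  if (!all(dim(bscan) == cfg$in_shape)) {
    stop(sprintf("input shape (%d, %d) does not match configured (%d, %d)",
                 nrow(bscan), ncol(bscan), cfg$in_shape[1], cfg$in_shape[2]))
  }
  p <- model$params
  cur <- as_feature_cube(bscan)
  enc_cb <- vector("list", dp); switches <- vector("list", dp)
  pooled_dims <- vector("list", dp)
  for (i in seq_len(dp)) {
    cb <- block_fwd(cur, p$enc[[i]], k, ws = keep)
    enc_cb[[i]] <- cb
    pooled_dims[[i]] <- dim(cb$out)
    pl <- cpp_maxpool2_fwd(cb$out)
    switches[[i]] <- pl$switches
    cur <- pl$y
  }
  bott_cb <- block_fwd(cur, p$bott, k, ws = keep)
  cur <- bott_cb$out
  dec_cb <- vector("list", dp); up_in <- vector("list", dp)
  for (i in rev(seq_len(dp))) {
    up_in[[i]] <- cur
    up <- cpp_upconv2_fwd(cur, p$dec[[i]]$up$w, p$dec[[i]]$up$b)
    skip <- enc_cb[[i]]$out
    cat_in <- array(c(up, skip), dim = dim(up) + c(0, 0, dim(skip)[3]))
    cb <- block_fwd(cat_in, p$dec[[i]], k, ws = keep)
    dec_cb[[i]] <- cb
    cur <- cb$out
  }
  logits <- cpp_conv2d_fwd(cur, p$head$w, p$head$b, 1L)
  prob <- stats::plogis(logits[, , 1] - logits[, , 2])
  out <- list(prob = prob)
  if (keep) {
    out$cache <- list(enc = enc_cb, bott = bott_cb, dec = dec_cb,
                      up_in = up_in, switches = switches,
                      pooled_dims = pooled_dims, final = cur, prob = prob)
  }
  out
}

backward_unet <- function(model, cache, dprob) {
  cfg <- model$cfg; k <- cfg$kernel_size; dp <- cfg$depth
  p <- model$params
  prob <- cache$prob
  ds <- dprob * prob * (1 - prob)
  dlog <- array(c(ds, -ds), c(dim(ds), 2L))
  rh <- cpp_conv2d_bwd(cache$final, p$head$w, dlog, 1L)
  g <- list(enc = vector("list", dp), bott = NULL, dec = vector("list", dp),
            head = list(w = rh$dw, b = rh$db))
  dcur <- rh$dx
  dskip <- vector("list", dp)
  for (i in seq_len(dp)) {
    r <- block_bwd(dcur, cache$dec[[i]], p$dec[[i]], k)
    co <- dim(cache$dec[[i]]$out)[3]
    dcat <- r$dx
    dup <- dcat[, , seq_len(co), drop = FALSE]
    dskip[[i]] <- dcat[, , co + seq_len(dim(dcat)[3] - co), drop = FALSE]
    ru <- cpp_upconv2_bwd(cache$up_in[[i]], p$dec[[i]]$up$w, dup)
    g$dec[[i]] <- c(list(up = list(w = ru$dw, b = ru$db)), r$g)
    dcur <- ru$dx
  }
  r <- block_bwd(dcur, cache$bott, p$bott, k)
  g$bott <- r$g
  dcur <- r$dx
  for (i in rev(seq_len(dp))) {
    dd <- cache$pooled_dims[[i]]
    dpooled <- cpp_unpool2(dcur, cache$switches[[i]], dd[1], dd[2])
    denc <- dpooled + dskip[[i]]
    r <- block_bwd(denc, cache$enc[[i]], p$enc[[i]], k)
    g$enc[[i]] <- r$g
    dcur <- r$dx
  }
  g
}

# recursive arithmetic over nested parameter lists
nested_map <- function(f, ...) {
  args <- list(...)
  if (is.list(args[[1]])) {
    out <- lapply(seq_along(args[[1]]), function(i) {
      do.call(nested_map, c(list(f), lapply(args, `[[`, i)))
    })
    names(out) <- names(args[[1]])
    out
  } else {
    do.call(f, args)
  }
}

#' Combined Dice and binary cross-entropy loss
#'
#' `L = (1 - (2|y ∩ ŷ| + 1) / (|y| + |ŷ| + 1)) + H(y, ŷ)`, with the set
#' cardinalities read as sums of positive-class probabilities (soft Dice, the
#' differentiable form) and `H` the mean binary cross entropy of the
#' positive-class probability against the ground truth, probabilities clamped
#' to `[1e-7, 1 - 1e-7]`. The `+1` smoothing makes an empty prediction
#' against an empty truth a perfect (zero) Dice term.
#'
#' @param pred Probability matrix in `[0, 1]`.
#' @param truth Binary matrix of the same shape.
#' @return List with `total`, `dice_term`, `bce_term`.
#' @export
dice_bce_loss <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth))) stop("prediction/truth shape mismatch")
  t <- (truth > 0) * 1
  s <- sum(pred * t); pp <- sum(pred); tt <- sum(t)
  dice_term <- 1 - (2 * s + 1) / (pp + tt + 1)
  pc <- pmin(pmax(pred, 1e-7), 1 - 1e-7)
  bce_term <- -mean(t * log(pc) + (1 - t) * log(1 - pc))
  list(total = dice_term + bce_term, dice_term = dice_term,
       bce_term = bce_term)
}

# gradient of dice_bce_loss w.r.t. the prediction probabilities
dice_bce_grad <- function(pred, truth) {
  t <- (truth > 0) * 1
  s <- sum(pred * t); pp <- sum(pred); tt <- sum(t)
  denom <- pp + tt + 1
  ddice <- -(2 * t * denom - (2 * s + 1)) / denom^2
  pc <- pmin(pmax(pred, 1e-7), 1 - 1e-7)
  dbce <- (-t / pc + (1 - t) / (1 - pc)) / length(pred)
  ddice + dbce
}

#' Train the segmentation network
#'
#' Mini-batch Adam (`lr` from the config, conventional
#' `beta1 = 0.9, beta2 = 0.999, eps = 1e-8`) on the combined Dice + BCE loss.
#' Inputs are intensity-normalized per B-scan; shuffling and initialization
#' are fully seeded, so two runs with one config are identical.
#'
#' @param model An [build_unet()] model.
#' @param samples List of `list(x = bscan matrix, y = binary truth matrix)`.
#' @param epochs,batch_size,learning_rate Optional overrides of the model
#'   config.
#' @param verbose Print per-epoch mean loss.
#' @return List with the trained `model` and a `history` data frame
#'   (epoch, mean_loss, dice_term, bce_term).
#' @export
train_unet <- function(model, samples, epochs = NULL, batch_size = NULL,
                       learning_rate = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "octga_unet"))
  if (length(samples) == 0) stop("training set is empty")
  cfg <- model$cfg
  epochs <- as.integer(epochs %||% cfg$epochs)
  batch_size <- as.integer(batch_size %||% cfg$batch_size)
  lr <- learning_rate %||% cfg$learning_rate
  xs <- lapply(samples, function(s) normalize_bscan(s$x))
  ys <- lapply(samples, function(s) (s$y > 0) * 1)
  for (x in xs) {
    if (!all(dim(x) == cfg$in_shape)) stop("sample shape mismatch with config")
  }
  p <- model$params
  # Adam runs on one flattened parameter vector; the nested list is rebuilt
  # in place after each step for the next gradient call
  theta <- unlist(p, use.names = FALSE)
  lens <- rapply(p, length, how = "unlist")
  relist_into <- function(plist, vec) {
    off <- 0L
    walk <- function(node) {
      if (is.list(node)) return(lapply(node, walk))
      nd <- length(node)
      seg <- vec[(off + 1L):(off + nd)]
      off <<- off + nd
      if (is.matrix(node)) dim(seg) <- dim(node)
      seg
    }
    walk(plist)
  }
  madam <- numeric(length(theta)); vadam <- numeric(length(theta))
  step <- 0L
  hist <- matrix(0, epochs, 3)
  with_seed(cfg$seed + 1L, {
    n <- length(xs)
    for (ep in seq_len(epochs)) {
      ord <- sample(n)
      tot <- c(0, 0, 0)
      for (b0 in seq(1, n, by = batch_size)) {
        idx <- ord[b0:min(b0 + batch_size - 1, n)]
        gacc <- NULL
        for (j in idx) {
          r <- cpp_unet_grad(xs[[j]], ys[[j]], model$params, cfg$depth,
                             cfg$kernel_size,
                             identical(cfg$precision, "single"))
          tot <- tot + c(r$loss, r$dice_term, r$bce_term)
          g <- unlist(r$grads, use.names = FALSE)
          gacc <- if (is.null(gacc)) g else gacc + g
        }
        gacc <- gacc / length(idx)
        step <- step + 1L
        madam <- 0.9 * madam + 0.1 * gacc
        vadam <- 0.999 * vadam + 0.001 * gacc^2
        bc1 <- 1 - 0.9^step; bc2 <- 1 - 0.999^step
        theta <- theta - lr * (madam / bc1) / (sqrt(vadam / bc2) + 1e-8)
        model$params <- relist_into(p, theta)
      }
      hist[ep, ] <- tot / n
      if (verbose) {
        message(sprintf("epoch %3d  loss %.4f (dice %.4f, bce %.4f)",
                        ep, hist[ep, 1], hist[ep, 2], hist[ep, 3]))
      }
    }
  })
  model$trained <- TRUE
  list(model = model,
       history = data.frame(epoch = seq_len(epochs), mean_loss = hist[, 1],
                            dice_term = hist[, 2], bce_term = hist[, 3]))
}

#' Predict a positive-class probability map
#'
#' @param object A trained (or untrained) `octga_unet`.
#' @param bscan Input matrix matching the configured shape; intensity
#'   normalized per scan before the forward pass.
#' @param channels If `TRUE`, return the full softmax output as an
#'   (height x width x 2) array of (positive, negative) class probabilities;
#'   otherwise just the positive-class map.
#' @param ... Unused.
#' @return Probability matrix of the input shape (or 2-channel array).
#' @export
predict.octga_unet <- function(object, bscan, channels = FALSE, ...) {
  p <- forward_unet(object, normalize_bscan(bscan))$prob
  if (channels) array(c(p, 1 - p), c(dim(p), 2L)) else p
}

#' Threshold a probability map into a binary mask
#'
#' Pixels strictly above the threshold are positive; a probability exactly at
#' the threshold is negative.
#'
#' @param p Probability matrix.
#' @param threshold Scalar in (0, 1); default 0.5.
#' @return Binary matrix.
#' @export
binarize <- function(p, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  (p > threshold) * 1
}

#' Save / load a model checkpoint
#'
#' The checkpoint is R's native serialized model plus a JSON sidecar with the
#' network configuration and a training history CSV when available.
#'
#' @param fit A `train_unet()` result or bare `octga_unet`.
#' @param prefix Path prefix; writes `<prefix>.rds`, `<prefix>.json` and
#'   optionally `<prefix>_history.csv`.
#' @return `prefix` invisibly (`save_unet`); the model (`load_unet`).
#' @export
save_unet <- function(fit, prefix) {
  model <- if (inherits(fit, "octga_unet")) fit else fit$model
  saveRDS(model, paste0(prefix, ".rds"))
  jsonlite::write_json(unclass(model$cfg), paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  if (!inherits(fit, "octga_unet") && !is.null(fit$history)) {
    utils::write.csv(fit$history, paste0(prefix, "_history.csv"),
                     row.names = FALSE)
  }
  invisible(prefix)
}

#' @rdname save_unet
#' @export
load_unet <- function(prefix) {
  path <- paste0(prefix, ".rds")
  if (!file.exists(path)) stop(sprintf("missing checkpoint file %s", path))
  readRDS(path)
}
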