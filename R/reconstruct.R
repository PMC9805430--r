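# Deconvnet inversion of the trained U-Net: block-by-block reconstruction of
# the input-space features driving the segmentation, using shared-weight
# transposed convolutions and the max-pooling switches recorded on the
# forward pass. No parameters are updated at any point.

#' Forward pass with recorded pooling switches
#'
#' Runs the standard forward pass and additionally records, for every 2x2
#' max-pooling layer, the location of each pooled maximum (the "switches"
#' needed to invert pooling). The probability output is identical to
#' [predict.octga_unet()].
#'
#' @param model An `octga_unet`.
#' @param bscan Input matrix (normalized per scan like `predict`).
#' @return List with `prob`, `switches` (one integer vector per pooling
#'   layer), `activations` (per-block outputs, forward order) and the full
#'   internal `cache`.
#' @export
forward_with_switches <- function(model, bscan) {
  fw <- forward_unet(model, normalize_bscan(bscan), keep = TRUE)
  acts <- c(lapply(fw$cache$enc, `[[`, "out"),
            list(fw$cache$bott$out),
            lapply(rev(fw$cache$dec), `[[`, "out"))
  names(acts) <- c(paste0("enc", seq_along(fw$cache$enc)), "bottleneck",
                   paste0("dec", rev(seq_along(fw$cache$dec))))
  list(prob = fw$prob, switches = fw$cache$switches, activations = acts,
       cache = fw$cache)
}

#' Invert max pooling using recorded switches
#'
#' Places each pooled value back at its recorded argmax location and zeroes
#' every other position.
#'
#' @param pooled (h x w x c) array of pooled values.
#' @param switches Integer switch vector recorded by
#'   [forward_with_switches()] for this layer.
#' @param out_shape Output (height, width) before pooling.
#' @return (out_shape, c) array.
#' @export
unpool <- function(pooled, switches, out_shape) {
  pooled <- as_feature_cube(pooled)
  if (length(switches) != length(pooled)) {
    stop("switch count does not match the pooled tensor")
  }
  if (any(out_shape[1:2] != 2 * dim(pooled)[1:2])) {
    stop("out_shape must be twice the pooled spatial extent")
  }
  cpp_unpool2(pooled, switches, out_shape[1], out_shape[2])
}

# Reverse a conv block: rectify, then apply the transposed convolution of
# each forward convolution in reverse order with shared weights and no bias.
# `gate_env`, when given, records (or replays) rectifier gates for the
# frozen-gate linear mode.
rev_conv_chain <- function(sig, convs, cins, k, gate_env = NULL) {
  for (j in rev(seq_along(convs))) {
    if (is.null(gate_env)) {
      sig <- pmax(sig, 0)
    } else {
      gate_env$i <- gate_env$i + 1L
      if (gate_env$replay) {
        sig <- sig * gate_env$gates[[gate_env$i]]
      } else {
        gate_env$gates[[gate_env$i]] <- (sig > 0) * 1
        sig <- pmax(sig, 0)
      }
    }
    sig <- cpp_conv2d_rev(as_feature_cube(sig), convs[[j]]$w, k, cins[j])
  }
  sig
}

#' Invert one convolution block
#'
#' Applies the rectifier and then the transposed convolution of each forward
#' convolution of the block in reverse order, reusing the forward kernels
#' (deconvnet semantics; biases are not re-applied on the reverse pass).
#'
#' @param signal (h x w x c) array matching the block's output.
#' @param block List of forward convolution layers in forward order, each
#'   `list(w = weight matrix, cin = input channels)`; e.g. an element of
#'   `model$params$enc`.
#' @param kernel_size Square kernel extent of the block's convolutions.
#' @return Array in the block's input space.
#' @export
invert_block <- function(signal, block, kernel_size = 3L) {
  convs <- block[names(block) %in% c("c1", "c2")]
  cins <- vapply(convs, function(cv) {
    cv$cin %||% (nrow(cv$w) / kernel_size^2)
  }, numeric(1))
  if (any(cins != round(cins))) stop("channel mismatch in block weights")
  rev_conv_chain(as_feature_cube(signal), convs, as.integer(cins),
                 kernel_size)
}

#' Reconstruct the salient input features behind a segmentation
#'
#' Starting from the last decoder block's output (the features feeding the
#' two-class 1x1 convolution), alternately inverts convolution blocks and
#' pooling layers down to the input space: decoder blocks are inverted with
#' shared-weight transposed convolutions, the concatenation of each skip
#' connection is split back into its up-convolution and encoder halves, the
#' encoder halves are routed into the encoder-side reverse path (summed where
#' the paths merge), and max-pooling is inverted with the recorded switches.
#' The model is never modified.
#'
#' @param model A trained `octga_unet`.
#' @param bscan Input B-scan matrix.
#' @param target What the default starting tensor represents:
#'   `"evidence"` (default) starts from the last decoder block's features
#'   scaled channel-wise by the class head's positive-minus-negative weights
#'   and restricted to pixels classified positive at the 0.5 rule — the
#'   decomposition of the positive-class logit margin over features and
#'   pixels, i.e. the part of the representation that produced the
#'   segmentation; `"features"` starts from the raw decoder features.
#' @param start Optional explicit starting feature tensor overriding
#'   `target` (used to probe the inversion as a map of the starting
#'   features).
#' @param gates Optional rectifier gate record from a previous call; when
#'   supplied the rectifiers are replayed as fixed masks, making the
#'   reconstruction a linear map of `start`.
#' @return An object of class `reconstruction_stack`: per-block
#'   reconstructions in reverse-forward order (`dec1 .. dec<d>`, bottleneck,
#'   `enc<d> .. enc1`), the last being an input-sized map; attributes carry
#'   the recorded `gates`.
#' @export
reconstruct_stack <- function(model, bscan, target = c("evidence", "features"),
                              start = NULL, gates = NULL) {
  stopifnot(inherits(model, "octga_unet"))
  target <- match.arg(target)
  cfg <- model$cfg; k <- cfg$kernel_size; dp <- cfg$depth
  p <- model$params
  fw <- forward_unet(model, normalize_bscan(bscan), keep = TRUE)
  cache <- fw$cache
  ge <- new.env()
  ge$i <- 0L
  ge$replay <- !is.null(gates)
  ge$gates <- gates %||% list()

  if (is.null(start)) {
    start <- cache$dec[[1]]$out
    if (target == "evidence") {
      wdiff <- p$head$w[, 1] - p$head$w[, 2]
      start <- sweep(start, 3, wdiff, "*") *
        array(fw$prob > 0.5, dim(start))
    }
  }
  sig <- start
  stack <- list()
  skip_rec <- vector("list", dp)
  for (i in seq_len(dp)) {
    co <- if (i == 1) cfg$base_channels else cfg$base_channels * 2^(i - 1)
    convs <- list(p$dec[[i]]$c1, p$dec[[i]]$c2)
    cat_rec <- rev_conv_chain(sig, convs, c(2L * co, co), k, ge)
    stack[[length(stack) + 1]] <- cat_rec
    names(stack)[length(stack)] <- paste0("dec", i)
    dup <- cat_rec[, , seq_len(co), drop = FALSE]
    skip_rec[[i]] <- cat_rec[, , co + seq_len(co), drop = FALSE]
    # invert the up-convolution (shared weights, no bias)
    if (ge$replay) {
      ge$i <- ge$i + 1L
      dup <- dup * ge$gates[[ge$i]]
    } else {
      ge$i <- ge$i + 1L
      ge$gates[[ge$i]] <- (dup > 0) * 1
      dup <- pmax(dup, 0)
    }
    sig <- cpp_upconv2_rev(as_feature_cube(dup), p$dec[[i]]$up$w, 2L * co)
  }
  cin_b <- cfg$base_channels * 2^(dp - 1)
  sig <- rev_conv_chain(sig, list(p$bott$c1, p$bott$c2),
                        c(cin_b, 2L * cin_b), k, ge)
  stack[[length(stack) + 1]] <- sig
  names(stack)[length(stack)] <- "bottleneck"
  for (i in rev(seq_len(dp))) {
    dd <- cache$pooled_dims[[i]]
    sig <- cpp_unpool2(as_feature_cube(sig), cache$switches[[i]], dd[1], dd[2])
    sig <- sig + skip_rec[[i]]
    cin <- if (i == 1) 1L else cfg$base_channels * 2^(i - 2)
    cout_half <- cfg$base_channels * 2^(i - 1)
    sig <- rev_conv_chain(sig, list(p$enc[[i]]$c1, p$enc[[i]]$c2),
                          c(cin, cout_half), k, ge)
    stack[[length(stack) + 1]] <- sig
    names(stack)[length(stack)] <- paste0("enc", i)
  }
  structure(stack, class = "reconstruction_stack", gates = ge$gates,
            prob = fw$prob)
}

#' @export
print.reconstruction_stack <- function(x, ...) {
  cat(sprintf("<reconstruction_stack: %d blocks, input-space map %d x %d>\n",
              length(x), dim(x[[length(x)]])[1], dim(x[[length(x)]])[2]))
  invisible(x)
}

#' Input-space saliency map of a reconstruction
#'
#' Rectifies the input-space reconstruction (negative values zeroed) and
#' max-normalizes it to `[0, 1]` for display and footprint-overlap tests.
#'
#' @param stack A [reconstruct_stack()] result.
#' @return Nonnegative matrix in `[0, 1]` with the input's shape.
#' @export
saliency_image <- function(stack) {
  r <- stack[[length(stack)]]
  if (length(dim(r)) == 3) r <- r[, , 1]
  r <- pmax(r, 0)
  mx <- max(r)
  if (mx > 0) r <- r / mx
  r
}

#' Energy contrast of reconstructions over lesion footprints
#'
#' For a phantom case and a trained model, measures the mean absolute
#' input-space reconstruction within each lesion's retinal region (footprint
#' columns between the ILM and C-S boundaries, over the B-scans the footprint
#' crosses). A converting lesion "passes" when its energy exceeds the mean
#' energy of the case's non-converting lesions (or, if there are none, the
#' background retina).
#'
#' @param model Trained `octga_unet` whose input shape matches the case's
#'   B-scans.
#' @param case A `phantom_case`.
#' @return Data frame with one row per lesion: `kind`, `converts`, `energy`,
#'   and for converting lesions `passes`.
#' @export
reconstruction_contrast <- function(model, case) {
  stopifnot(inherits(case, "phantom_case"))
  ds <- dim(case$oct)
  in_shape <- model$cfg$in_shape
  sh <- in_shape[1] / ds[1]; sw <- in_shape[2] / ds[2]
  any_fp <- Reduce(`+`, lapply(case$lesions, `[[`, "enface_footprint"))
  depths <- which(colSums(any_fp > 0) > 0)
  sal <- list()
  for (d in depths) {
    x <- case$oct[, , d]
    if (!all(dim(x) == in_shape)) x <- resize_image(x, in_shape, "bilinear")
    st <- reconstruct_stack(model, x)
    r <- st[[length(st)]]
    sal[[as.character(d)]] <- abs(if (length(dim(r)) == 3) r[, , 1] else r)
  }
  energy_of <- function(fp) {
    tot <- 0; npx <- 0
    for (d in intersect(which(colSums(fp > 0) > 0), depths)) {
      sl <- sal[[as.character(d)]]
      for (w in which(fp[, d] > 0)) {
        wi <- min(max(1L, as.integer(ceiling(w * sw))), in_shape[2])
        rr <- max(1L, as.integer(ceiling((case$layers$ilm[w, d] + 1) * sh))):
          min(in_shape[1], as.integer(ceiling((case$layers$cs[w, d] + 1) * sh)))
        tot <- tot + sum(sl[rr, wi]); npx <- npx + length(rr)
      }
    }
    if (npx == 0) NA_real_ else tot / npx
  }
  kinds <- vapply(case$lesions, `[[`, "", "kind")
  conv <- vapply(case$lesions, `[[`, TRUE, "converts")
  energy <- vapply(case$lesions, function(l) energy_of(l$enface_footprint),
                   numeric(1))
  if (any(!conv)) {
    ref <- mean(energy[!conv])
  } else {
    bg <- (any_fp == 0) * 1
    ref <- energy_of(bg)
  }
  data.frame(kind = kinds, converts = conv, energy = energy,
             reference = ref, passes = ifelse(conv, energy > ref, NA))
}
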