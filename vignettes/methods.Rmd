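---
title: "Predicting geographic atrophy from baseline OCT and reconstructing its drivers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting geographic atrophy from baseline OCT and reconstructing its drivers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

In dry age-related macular degeneration (AMD), geographic atrophy (GA) is
delineated clinically on fundus autofluorescence (FAF), while the baseline
biomarkers that precede it — drusen, hyper-reflective foci (HRF), subretinal
drusenoid deposits (SDD) — live in 3D spectral-domain OCT. `octga` implements
a longitudinal, cross-modal pipeline: GA annotations from a *follow-up* FAF
visit are transferred into *baseline* OCT coordinates and used as ground
truth to train a segmentation network on baseline B-scans. A network that
succeeds at this task has implicitly located the baseline features that
precede atrophy; inverting it with a deconvnet then makes those features
visible.

The pipeline has five stages:

1. **synth** — seeded retinal phantoms (in place of private patient data);
2. **prepare** — keypoint registration of the follow-up annotation into the
   baseline en-face frame and extrusion into per-B-scan masks;
3. **train** — a square-filter U-Net under a Dice + binary cross-entropy
   loss;
4. **reconstruct** — shared-weight transposed-convolution inversion of the
   trained network with max-pooling switches;
5. **evaluate** — en-face aggregation, 2-/3-class Otsu binarization selected
   by Dice, confusion-matrix metrics, k-fold cross-validation.

## Label transfer

Follow-up FAF images are registered to the baseline en-face frame by a
projective homography fitted to manually selected (here: synthetically
placed) keypoint correspondences with the normalized direct linear
transform: both point sets are centered and scaled to mean distance
$\sqrt2$, the homogeneous $2n\times9$ system is solved by SVD, and the
normalizations are undone. Projective was chosen over affine because it
subsumes it and matches the geometry of two different imaging devices
viewing a (locally) planar fundus. With noiseless consistent pairs the fit
is exact; the test suite checks recovery of 1,000 random homographies to
relative error $10^{-6}$.

Warping is inverse-mapping resampling — bilinear for intensities, nearest
neighbor (and re-binarization) for masks, out-of-frame samples 0. The
registered annotation, resampled to the volume's lateral grid, is extruded
through each A-scan column between the inner limiting membrane (ILM) and
choroid–sclera (C-S) boundaries, read as a closed row interval. Extrusion
and collapse are exact set inverses (`collapse(extrude(m)) == m`), which
the suite verifies on random masks and layer geometries. Layer boundaries
are consumed as input; they are known exactly for phantoms.

## The segmentation network

`build_unet()` constructs an encoder–decoder with square $3\times3$
filters, two convolutions + rectifier per block, $2\times2$ max pooling
with channel doubling, $2\times2$ stride-2 up-convolutions, concatenation
skip connections and a final $1\times1$ convolution to two classes with a
softmax. The loss is

$$L = \left(1 - \frac{2|y\cap\hat y| + 1}{|y| + |\hat y| + 1}\right) +
H(y, \hat y),$$

with the set cardinalities read as sums of positive-class probabilities
(soft Dice — the differentiable reading required for gradient descent), the
$+1$ smoothing constant as printed, and $H$ the mean binary cross-entropy
of the positive-class probability, clamped to $[10^{-7}, 1-10^{-7}]$.
Training uses Adam at learning rate $10^{-4}$ (the published setting) with
conventional moments, mini-batches, fully seeded initialization and
shuffling. B-scans are min-max normalized per scan; probabilities are
binarized by a strict `> 0.5` rule (a pixel exactly at the threshold is
negative).

The forward/backward pass exists twice: a modular R composition of the
convolution kernels (used for prediction and inversion, and as the
reference in tests), and a fused C++ training step verified against it to
$10^{-12}$; training arithmetic defaults to single precision, the usual
choice for network training. Gradients are additionally checked against
central finite differences.

## Deconvnet reconstruction

During the forward pass every pooling layer records the location of each
maximum (the *switches*). The reverse pass inverts the network block by
block: the rectifier is applied to the incoming signal, then the transposed
convolution of each forward convolution in reverse order with *shared*
weights and no biases; pooling is inverted by placing values at their
switches and zeroing the rest; the concatenated skip reconstruction is
split back into its up-convolution and encoder halves, with the encoder
half summed into the encoder-side reverse path. No parameter is ever
updated, which a checksum test enforces. With switches and rectifier gates
frozen from one pass, the whole reconstruction is a linear map of the
starting tensor — verified by superposition.

**Starting tensor.** The default start is not the raw decoder output but
its *positive-class evidence*: the last decoder block's features scaled
channel-wise by the class head's (positive − negative) weights and
restricted to pixels classified positive. This is the exact decomposition
of the positive-class logit margin over channels and pixels — it inverts
"what produced the segmentation". The raw features are reconstructible via
`target = "features"`. This choice matters: a small network under heavy
class imbalance may encode atrophy precursors by feature *absence*
(background-structure channels suppressed at lesions), in which case a raw
start reconstructs background anatomy rather than lesions. For the same
reason the study network uses 8 base channels: at 4 the network still
segments well but learns a pure suppression code with no positive-evidence
channels left to invert.

`saliency_image()` rectifies the input-space reconstruction and
max-normalizes it; `reconstruction_contrast()` turns the package's
qualitative claim — reconstructions highlight converting druse clusters,
not isolated HRF/SDD — into a number: the mean absolute input-space
reconstruction inside each lesion's retinal region (footprint columns
between ILM and C-S), with a converting lesion "passing" when its energy
exceeds the mean over the case's non-converting lesions.

## Evaluation

Per-B-scan probability maps are column-averaged along the height axis,
stacked over depth into a width × depth map, and bilinearly resized to the
square 512 × 512 en-face frame. Binarization computes the 2-class Otsu
threshold and the upper threshold of the 3-class variant (both maximizing
between-class variance over a 256-bin histogram, the 3-class case by
exhaustive search over bin pairs) and keeps whichever candidate has the
higher Dice against the registered truth, ties to 2-class. Threshold
selection against ground truth reproduces the published protocol but is an
*optimistic-evaluation caveat*: the chosen operating point uses the truth.
Dice for this selection uses no smoothing and defines empty-vs-empty as 1,
so spurious positives on empty truths are never rewarded.

Metrics come from pixelwise confusion counts: accuracy, sensitivity,
specificity, and overlap in its Jaccard reading
$TP/(TP+FP+FN)$ — the printed definition "overlap = TP" is inconsistent
with the same source's reported overlap values, so the Jaccard reading is
adopted and the raw fraction $TP/\text{total}$ is emitted alongside as
`tp_fraction`, without asserting either is the original computation. A
metric with a zero denominator is `NA`, never 0 or 1. Cross-validation
partitions cases (never B-scans) into k near-equal seeded folds; the
primary combined report is the mean over held-out cases, with the mean of
fold means also reported.

## The phantom

Real longitudinal OCT/FAF pairs are private, so the package generates its
own: layered volumes (vitreous, inner retina, a bright RPE band, choroid to
the C-S junction, sclera) on smooth seeded surfaces, with multiplicative
speckle $(1 + \sigma N(0,1))$ clipped to $[0,1]$ — a cheap stand-in for
OCT's granularity, not a physical speckle model. Three lesion classes are
placed on disjoint en-face footprints: druse clusters as dome-shaped RPE
elevations filled with medium-reflective material, HRF as small bright
intraretinal blobs, SDD as thin bright deposits just above the RPE. The
generative conversion rule is fixed: *druse clusters convert to GA, HRF and
SDD do not* — the finding the reconstruction property must recover, wired
in so the phantom has a known answer. The follow-up annotation is the union
of converting footprints dilated by a configurable margin, pushed into the
follow-up frame by the inverse of a drawn planar misalignment (translation
+ rotation + mild projective perturbation, bounded to keep the image in
frame). Vessel-like Bezier fiducials shared by both FAF images provide
keypoints that correspond exactly under the true transform.

Defaults are desk-scale: 256 × 128 × 32 volumes (the native clinical
geometry of 1024 × 512 × 128 is configurable), 3 druse clusters of radius
7–12 px, 3 HRF of 2–4 px, 2 SDD, speckle σ = 0.08, misalignment up to
10 px / 4° / $5\times10^{-5}$ projective, conversion margin 2 px. Radii are
width-axis pixels; the depth axis is scaled by the width/depth ratio so
footprints are physically isotropic. What the phantom does *not* emulate:
photorealistic speckle statistics, vascular flow, real lesion morphometry
(no quantitative morphometry is published for these data), eye movement or
acquisition artifacts, or progression dynamics beyond the single binary
rule. Passing tests therefore show the pipeline recovers *known planted
structure under the stated noise*, not clinical performance.

## Study protocol and problem sizes

The repository's end-to-end property test runs 24 phantoms at
256 × 128 × 32 through fourfold cross-validation with a depth-3,
8-base-channel network for 30 epochs (Adam, $10^{-4}$, batch 1). The
network ingests B-scans bilinearly resampled to 128 × 64 — the en-face
evaluation stays at 512 × 512 against the registered truth — and each
training epoch draws 16 of the 32 B-scans per case, stratified so that
about half carry positive labels. These sizes are the package's chosen
desk-scale study; they hold the held-out combined accuracy above 0.9 and
Jaccard overlap above 0.5, with the reconstruction energy contrast holding
for at least 80% of held-out converting lesions. `scripts/acceptance.R`
re-runs a 16-case version of the same protocol from scratch.

## Numerical choices and degenerate inputs

- Homography fitting refuses fewer than 4 pairs and rank-deficient
  (collinear) configurations by inspecting the second-smallest singular
  value.
- Resampling uses the half-pixel-center convention; integer nearest-neighbor
  upscales are exact block replications, and the matching downscale inverts
  them — this makes the phantom's annotation/footprint identities exact.
- Otsu thresholding rejects constant maps by name; 3-class thresholds are
  strictly increasing; ties in threshold selection go to the 2-class
  variant.
- Zero-denominator metrics are `NA` and are dropped (`na.rm`) from fold
  averages.
- Training and the pipeline are bitwise reproducible run-to-run under one
  seed on a fixed BLAS; all randomness (phantoms, shuffling, fold
  assignment, initialization) funnels through explicit seeds.
- The memorization test (4 lesion-bearing B-scans, 50 epochs) uses a higher
  learning rate ($2\times10^{-3}$) and a background-prior head bias: at the
  published $10^{-4}$ the 200 available Adam steps cannot move freshly
  initialized weights far enough to overfit, which is a statement about
  step counts, not about the trainer.

## Known limitations

- The ground-truth-dependent Otsu selection inflates metrics relative to a
  truth-free operating point (documented above; faithful to the published
  protocol).
- The phantom's conversion rule is deterministic and lesion-type-pure;
  mixed or ambiguous lesions are not modeled.
- The deconvnet start is one defensible reading of "positive" feature
  reconstruction; other saliency families (guided backpropagation,
  gradient × input) are deliberately out of scope.
- At desk scale the network is small; absolute metric values are not
  comparable to clinical-scale results and are not meant to be.
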