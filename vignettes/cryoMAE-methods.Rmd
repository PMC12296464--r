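---
title: "cryoMAE: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cryoMAE: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the science inside cryoMAE: what each stage of the
pipeline assumes, which parameters matter and why their defaults are what
they are, what the synthetic generator does and does not emulate, and
where we made genuinely open design choices.

## The problem and the model

A cryo-EM micrograph is a very low-SNR 2-D image containing many randomly
oriented projections ("particles") of a molecule in vitreous ice. The
noise level varies within and between micrographs (ice thickness,
exposure), which is what breaks supervised pickers trained on one dataset
when applied to another. cryoMAE's premise is that a representation
learned purely by masked reconstruction of the micrographs themselves
already separates particle regions from background, so picking reduces to
clustering that representation.

The pipeline has four stages — preprocessing, representation,
segmentation, post-processing — each exposed as ordinary functions so any
stage can be inspected or replaced.

## Preprocessing

At each position the mean and standard deviation over a disc of the
particle diameter are computed by FFT cross-correlation and used to
standardize the image. Two numerical choices matter:

* **Boundary convention.** The local statistics use periodic boundaries —
  the FFT-native convention, matching the Fourier definition of the
  operator exactly. This makes the operator identical to a brute-force
  sliding-window sum with wrap-around, which is how the test suite checks
  it (to 1e-6 on images up to 32×32). Edge cells therefore mix opposite
  borders; for typical 4k-pixel micrographs with a ~100-px particle
  diameter the affected band is a few percent of the image and is further
  protected by the border filter at the end of the pipeline.
* **Zero-variance guard.** `sigma` is floored at `1e-6` times the global
  standard deviation (absolute floor 1e-12), so constant regions map to 0
  rather than NaN, and the normalization is exactly invariant to affine
  intensity changes `a*X + b`.

Normalization and enhancement run at the **original** resolution, because
the circular mask is defined by the physical particle diameter; the resize
to the working resolution happens afterwards. The enhancement chain is
adaptive Wiener (5×5 window) → min–max rescale → CLAHE (clip limit 2, 8×8
tiles) → guided filter (radius `diameter/4`, regularization 1e-2) with the
CLAHE image as guide. These four parameters are exposed in `runConfig()`
but rarely need changing; they control denoising strength and local
contrast, not the method's semantics. Resizing uses bilinear
interpolation with a Gaussian anti-alias pre-blur on downscale, and
records per-axis scale factors so picked coordinates can be mapped back.

## The masked autoencoder

Working images are cut into tiles (64 px at full scale) and tiles into
8×8-pixel tokens. Per tile, exactly `round(0.5 * tokens)` tokens are
masked, drawn uniformly and independently per tile, so masking is spread
evenly across the micrograph. The encoder is a pre-LayerNorm transformer
of width 192 (depth 6, 3 heads at full scale); the decoder is a narrower
transformer (width 96, depth 2) that reconstructs pixel tokens from the
projected latents plus a learned mask token. The loss is the MSE over the
masked tokens' pixels only — the standard masked-autoencoder objective.

Design choices we made where the design was genuinely open:

* **Position-free encoder.** Token positions are supplied only to the
  decoder (fixed 2-D sine–cosine encodings); the encoder receives none.
  With additive positional encodings on the encoder we observed that the
  k-means stage partitioned the latent grid by within-tile token position
  — every cluster contained exactly one quarter of the grid — rather than
  by content, and end-to-end recovery failed. A set encoder makes the
  latent of a token depend only on the token's pixels and its tile
  context, which is precisely the translation-consistency the clustering
  stage relies on. The decoder still knows where each token sits, so the
  reconstruction task is unchanged.
* **Optimizer.** AdamW (beta2 = 0.95, weight decay 0.05 on weight
  matrices), peak learning rate 1.5e-4 with 5% linear warm-up and cosine
  decay, batches of 64 tiles. All seeded; training is bit-reproducible in
  single-threaded mode.
* **Checkpoint selection.** 20% of tiles are held out; the checkpoint with
  the lowest validation reconstruction loss is returned. Validation masks
  are drawn once so the criterion is comparable across epochs. This keeps
  model selection label-free, consistent with the self-supervised premise.
* **Architecture depths.** The latent width 192 and the 50% masking are
  fixed by the method; encoder depth 6 / decoder depth 2 / token size 8
  are configurable defaults sized for CPU training.

At inference no masking is applied; every token of every tile is encoded
and the latents form a spatial grid (128×128 at full scale, stride 8 px).
Clustering operates on the raw 192-d vectors without feature scaling —
the encoder output already is the clustering space.

## Segmentation by clustering

k-means with k = 4 (k-means++ initialization, 10 restarts, Lloyd
iterations, all seeded; centers sorted lexicographically so cluster
indices are reproducible) is fitted on latents pooled over the training
micrographs, capped at 200,000 vectors by a seeded uniform subsample. The
particle cluster is identified with one reference micrograph and its
particle mask: the mask is downsampled to the latent grid (a cell is
particle if at least half its pixels are), and the cluster maximizing the
precision-style ratio |cells ∩ particle| / |cells| is selected — robust
when cluster sizes are imbalanced.

Each test micrograph is then refined with its own k-means at k = 3, 4, 5:
at each level the cluster with the greatest overlap with the previous
particle set is kept. **Overlap score.** We score overlap as the contained
fraction |C ∩ prev| / |C| — the purity of the candidate cluster with
respect to the previous particle set — with ties broken by larger
intersection, then smaller cluster. Two simpler readings fail in
practice: a raw intersection count lets a large background cluster that
swallows part of a noisy previous set outscore a pure particle cluster
(we observed refinement drifting entirely into background this way), and
Jaccard similarity inherits a milder version of the same failure whenever
the initial particle set is bloated by micrograph-specific noise — the
exact condition the refinement exists to correct. The purity score makes
each level a monotone denoising step, which also matches the empirical
precision-up / recall-down behaviour as the final cluster count grows.
An empty initial particle set yields an empty mask with a warning, not an
error, so batch runs survive degenerate micrographs.

## Post-processing

The binary grid mask is smoothed with a uniform 3×3 mean kernel (zero
padding) — enough to fill single-cell holes — and bilinearly upsampled to
the working frame. The threshold applied to the upsampled map is chosen
from 101 evenly spaced candidates in [0, 1] as the one whose foreground
fraction is closest to the target of 4% of the image area, the particle
occupancy statistic of typical training data; ties resolve to the
stricter threshold. Thresholding happens after upsampling (the smoothed,
interpolated map is the object being pruned). 8-connected components
become candidates with centroid centers, equal-area-disc radii and mean
map value as score. Filters apply in the order size → border → neighbours:
radius above 1.5× the particle radius (merged blobs), centers within half
a diameter of an edge (truncated particles), then greedy non-maximum
suppression in descending score at one diameter. The order matters only
in that suppression should not waste a slot on a particle another filter
would discard.

All coordinates are 0-based with x = column, y = row and origin at the
top-left pixel, in the original micrograph frame when written to disk
(STAR `rlnCoordinateX/Y` or EMAN box). Whether coordinate files in the
wild are 0- or 1-based is genuinely ambiguous; we standardize on 0-based
and document it here.

## Evaluation

Box IoU between axis-aligned squares of side = particle diameter; greedy
one-to-one matching in descending IoU; a pair is a true positive only if
IoU ≥ 0.6 (the threshold is configurable — an alternative reading,
"overlap of more than 60% of the surface area", is supported by setting
`tpIoU` accordingly, but IoU ≥ 0.6 is the default). Precision with zero
predictions is defined as 0 so F1 stays defined. The greedy matcher
equals an exhaustive maximum-cardinality matcher on all tested instances
(up to 6×6, jittered configurations); the exhaustive matcher exists only
in the test suite.

## The synthetic generator

`generateMicrograph()` emulates the features the pipeline actually
exploits: dark disc-shaped particles of a known diameter (higher density →
lower intensity), soft edges (Gaussian-blurred indicator, sigma =
diameter/8), i.i.d. Gaussian background noise, and a low-frequency linear
illumination ramp in a random direction standing in for ice-thickness
gradients. Placement is rejection sampling with a minimum separation of
1.2 diameters and a half-diameter border margin. It does **not** emulate
CTF ringing, structured particle interiors, orientation-dependent
projections, aggregates, or contamination — so passing tests demonstrate
that the machinery (normalization, representation, clustering, extraction,
metrics) is correct and self-consistent, not that real-data performance
matches any published figure. Defaults (contrast 3.5 sd, noise sd 1, ramp
amplitude 1, ~4% area occupancy) are chosen to sit in the regime the
method targets: particles visible but far from trivially separable from
noise, occupying the area fraction the thresholding step assumes.

## Problem sizes used by the tests

The test and acceptance suites run a desk-scale profile: 256-px working
images, 32-px tiles (64 per micrograph), 8-px tokens, encoder depth 3 and
30 epochs, with 5 training and 5 held-out synthetic micrographs of six
24-px particles each (~4% area). These sizes preserve every structural
ratio of the full-scale configuration (tile/token geometry, masking,
cluster counts, thresholds) while keeping a complete train-pick-evaluate
cycle in the minutes range on a single CPU. Full-scale defaults
(1024/64/8, depth 6, 400 epochs) are what `runConfig()` returns.

## Known limitations

* Picking quality degrades gracefully but noticeably on crowded
  micrographs where particles touch: the 8-connected extraction merges
  blobs and the radius filter then discards them.
* The area-targeted threshold assumes the ~4% occupancy statistic
  transfers from training data; datasets with very different particle
  densities need `targetFraction` adjusted.
* The refinement's purity score can, in principle, latch onto a very
  small spurious cluster that lies inside the previous particle set;
  tie-breaks and the k ≤ 5 default make this rare, but it is the price of
  robustness against background drift.
* Training is CPU-bound R; full-scale 400-epoch runs on hundreds of
  micrographs are practical only with patience. The desk profile exists
  for everything else.
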