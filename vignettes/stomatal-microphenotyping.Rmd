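---
title: "Stomatal microphenotyping with a hierarchical-transformer segmenter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stomatal microphenotyping with a hierarchical-transformer segmenter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stomatools)
```

## The problem

Stomata — pore complexes bounded by two guard cells on the leaf epidermis —
control gas exchange and transpiration. Their size and density are
quantitative traits of direct agronomic interest, but measuring them from
leaf micrographs by hand (or semi-automatically in ImageJ) is slow and
subjective. `stomatools` implements an automated pipeline for cereal-leaf
micrographs: a semantic-segmentation model assigns every pixel to one of
three classes (background = 0, stoma = 1, pore = 2), and a morphometry stage
converts the resulting mask into per-stoma phenotypes — length, width, area
and count.

Everything is testable end-to-end without real micrographs: a synthetic
generator renders microscope-like fields with exact ground truth, so the
whole pipeline can be validated by parameter recovery.

## The segmentation model

The model is a hierarchical transformer in the mix-transformer (MiT /
SegFormer) convention with an additional cross-layer pyramid attention
block:

1. **Overlapping patch embedding.** A 7×7 convolution with stride 4 and
   padding 3 maps the RGB input to the 1/4-resolution token grid.
2. **Four transformer stages** at 1/4, 1/8, 1/16 and 1/32 resolution with
   channel widths 64/128/320/512 (full preset). Each block is pre-norm
   spatial-reduction self-attention — keys and values are average-pooled by
   per-stage ratios 8/4/2/1 before projection, which keeps attention cost
   linear in image size — followed by a Mix-FFN (linear → 3×3 depthwise
   convolution on the token grid → GELU → linear). Stages are connected by
   overlapping 3×3 stride-2 merges.
3. **Cross-layer pyramid attention (CFPT).** The four feature levels are
   channel-aligned by lateral 1×1 projections and spatially aligned on the
   1/16 grid (average pooling down, bilinear up — the channel-reconstruction
   step). Two attention paths then run over the stacked representation:
   *channel attention* (CCA), where tokens are the aligned channels and the
   attention matrix is the scaled Gram matrix of channel profiles, and
   *spatial attention* (CSA), where tokens are grid positions with learned
   query/key/value projections. Their outputs are combined linearly,
   redistributed to the original grids, and added residually through
   per-level output projections. Because the block is residual, zeroing the
   output projections makes it an exact identity — a property the test suite
   exercises.
4. **All-MLP decoder.** Each level is projected to a common width (256 full,
   64 tiny), bilinearly upsampled to the 1/4 grid, concatenated, passed
   through two parallel MLP branches, fused by a linear layer, classified,
   and upsampled to full resolution, giving an (H, W, K) logit tensor. The
   predicted mask is the per-pixel argmax with ties broken toward the lower
   class index.

Design choices that the architecture description leaves open, decided here
once: CFPT is applied to the encoder's four-level output (cross-layer
attention is only defined over a pyramid, which does not exist before
encoding); bilinear resampling uses the align-corners-false convention
everywhere; attention uses a single head per stage; weights are initialized
truncated-normal (sd 0.02, clipped at 2 sd) with zero biases, fully
determined by a seed. Inputs whose sides are not divisible by 32 are
rejected rather than silently padded — the caller decides how to pad.

The forward and backward passes run on a small reverse-mode autodiff tape
written for this package (dense matrices, BLAS matmuls, sparse resampling
operators, fused batched attention). Every analytic gradient is validated
against central finite differences in the test suite.

## Training

The loss is a **hybrid**: `w_ce · CE + w_dice · (1 − mean soft Dice)`, with
default weights (1, 1) and optional per-class CE weights. Cross-entropy
alone under-weights the small pore regions; the Dice term counteracts that
foreground/background imbalance. The loss is non-negative and tends to zero
exactly in the saturated correct-logit limit.

The optimizer is AdamW (β = 0.9/0.999, weight decay 0.01 applied to
projection matrices only). Two learning-rate schedules are implemented,
since both appear in practice: a fixed per-epoch decay (rate ×0.8 after
every epoch) and a plateau schedule (×0.8 only when the smoothed per-epoch
validation loss has not improved for 5 epochs). The plateau schedule is the
default: a strict 0.8-per-epoch decay would shrink the rate by ~10^-19 over
200 epochs, so it is only useful for short runs. The configured defaults —
initial rate 6e-5, batch 8, 200 epochs — describe the full-scale regime;
the desk-scale runs in this package use the tiny preset with rate 1e-3, the
standard AdamW magnitude for small transformers trained from scratch (6e-5
is a fine-tuning rate and would need far more than 30 epochs from random
initialization).

Bookkeeping follows the train-diagnostics convention: raw and EMA-smoothed
(α = 0.1) training and validation losses per batch, and learning rate,
pixel precision and MIoU on the validation partition per epoch. Runs are
bit-reproducible from the config seed. A k-fold splitter (balanced folds,
sizes differing by at most one) supports cross-validation over the
train+validation pool, leaving the test partition untouched.

## Synthetic fields: what they emulate, and what they do not

`stoma_field_spec()` describes a field of view; its defaults are the study
conditions the package targets: 1600 × 1200 px fields holding 19–23
non-overlapping stomata with long axes 100–140 px and short axes 55–80 px —
the scale of wheat-leaf micrographs at 550× magnification, where mean
stomatal length/width are roughly 120/67 px and a field holds ~19–23
stomata. Each stoma is rendered as two tangent elliptical guard-cell lobes
with an interior pore ellipse (pore axes 0.4× the stoma axes), so the
object keeps the elongated morphology the minimum-rectangle measurement
assumes while the mask still contains the nested pore class. Objects are
placed by rejection sampling under a bounding-circle separation test;
over-dense specifications fail loudly. Appearance is textured Gaussian
noise (smoothed, amplitude 8 intensity units), a corner-to-corner
illumination ramp, per-object brightness jitter and a darker guard-cell
seam, rendered to greenish RGB. Calibration is left in pixel units: the
pixel-to-µm factor at 550× is instrument-specific, so traits are reported
in px/px² and a user-supplied `pixel_area` scalar converts them.

The generator does **not** render epidermal cell walls, trichomes, dust, or
focus gradients. Passing tests therefore demonstrate that the architecture
can learn and that the measurement pipeline is correct — not that the
shipped configuration reaches any particular accuracy on real micrographs.

Augmentation mirrors standard practice: random rotation, isotropic scaling,
flips, smooth elastic deformation and additive image noise, applied with
identical geometry to image and mask. Masks are resampled
nearest-neighbour (fractional labels are meaningless), images bilinearly;
regions exposed by the transform are filled with background (label 0 / mean
background intensity). The default expansion factor is 10 variants per
source (the original counts as one), matching a 1,260 → 12,600 expansion.

## Dataset bookkeeping

Splits use largest-remainder apportionment of the normalized 7:2:1 ratios —
for 12,600 samples, exactly (8820, 2520, 1260) — with a seeded permutation.
When samples are augmented variants, the default is to split **by source
group**, so siblings never straddle partitions; ungrouped splitting (which
reproduces exact sample-level counts, at the cost of sibling leakage) is
available by omitting the groups. Masks are stored as single-channel 8-bit
PNGs whose pixel values are the raw labels; round-trips are bit-exact and
reads validate the label range.

## Numerical and degenerate-case choices

* MIoU excludes classes absent from both masks (0/0 unions); it errors only
  if every class is empty-union.
* Pixel precision counts correct pixels jointly over classes (micro
  accuracy-style), matching the confusion-count definition it comes from.
* R² is reported in two conventions: *agreement* (residuals about the
  identity line; the default, appropriate for validating automated
  measurements against a reference) and *regression* (squared Pearson).
* Minimum rectangles: rotating calipers over the convex hull (the optimum
  has a side collinear with a hull edge, so the scan is exact). Points are
  pixel centers; reported sides are extents plus one pixel, so a single
  pixel is a 1×1 rectangle and an axis-aligned w×h block measures w×h.
* Instance separation uses 8-connected components; touching stomata merge
  into one object — a documented limitation, irrelevant for well-separated
  fields. Components under `min_size` (default 50 px²) are dropped as
  specks. Border-touching objects are counted but flagged so users can
  filter them.
* Trait measurement defaults to the union of stoma and pore classes: the
  pore lies inside the stoma, and excluding it would bias area low.
  Stoma-only and pore-only policies are available.

## Problem sizes used in the shipped checks

The package's own validation runs at desk scale, chosen to exercise every
code path with exact oracles: synthetic fields from 96² to 1600×1200 px;
geometry checks against a 0.1°-grid brute-force rectangle search; and a
training run of the tiny preset (64 training / 8 held-out fields of
128×128 px, 30 epochs, batch 8) that reaches held-out MIoU ≥ 0.9 — the
learning-progress property, not a claim about full-scale accuracy.
`scripts/acceptance.R` re-runs all of these from scratch and writes the
resulting numbers as JSON.

## Known limitations

* Single-head attention and a fixed two-branch decoder; head counts and
  branch counts are not configurable.
* No GPU path; the full preset at 1600×1200 is for inference experiments,
  not practical training, on CPU.
* The plateau/epoch-decay duality reflects genuinely ambiguous practice;
  both are first-class, and histories record which was active.
* Aperture state (open/closed) and guard-cell vs pore sub-analysis beyond
  the class policies are out of scope.
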