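# stomatools

Automated microphenotyping of stomata in leaf micrographs. The package
segments micrographs into background / stoma / pore with a hierarchical
transformer and converts the masks into per-stoma phenotypes — length,
width, area and count — the traits used for screening water-use efficiency
in cereal breeding panels.

**For whom:** plant phenotyping and quantitative-genetics groups who need
per-stoma trait tables from micrographs (e.g. as GWAS phenotypes), and
method developers who want a fully testable, dependency-light reference
implementation of a SegFormer-style segmenter with a cross-layer feature
pyramid attention block.

## What is inside

* **Model** (`model_config`, `build_model`, `encoder_forward`,
  `cfpt_forward`, `decoder_forward`, `predict_mask`): overlapping 7×7/4
  patch embedding; four transformer stages at 1/4–1/32 resolution with
  channels 64/128/320/512, spatial-reduction self-attention and Mix-FFN;
  a residual cross-layer pyramid attention block (channel attention over
  aligned channel tokens + spatial attention over 1/16-grid tokens); and an
  all-MLP decoder emitting an (H, W, K) logit tensor. A `"tiny"` preset
  (16/32/64/128 channels) trains in minutes on one CPU. Forward/backward
  run on a reverse-mode autodiff tape included in the package, gradient-
  checked against finite differences.
* **Training** (`train_config`, `train_model`, `hybrid_loss`,
  `lr_at_epoch`, `smooth_losses`, `kfold_assign`): hybrid
  cross-entropy + soft-Dice loss; AdamW; per-epoch ×0.8 decay or plateau
  schedule; per-batch raw and EMA-smoothed train/validation losses;
  per-epoch precision and MIoU; bit-reproducible from a seed.
* **Metrics** (`pixel_precision`, `mean_iou`, `r_squared`, `rmse`,
  `trait_correlation`): pixel precision Pre = True_p / (True_p + False_p);
  MIoU = mean over classes of |A_pred ∩ A_gt| / |A_pred ∪ A_gt|; agreement
  and regression R²; Pearson correlation matrices with t-test p-values.
* **Traits** (`extract_stoma_objects`, `min_area_rect`, `measure_traits`,
  `mask_to_traits`): 8-connected components, Moore boundary tracing,
  rotating-calipers minimum-area rectangles (length = long side, width =
  short side), pixel-count areas, border flags.
* **Synthetic data** (`stoma_field_spec`, `generate_sample`,
  `augment_sample`, `augment_dataset`): microscope-like fields of two-lobed
  stomata with interior pores and exact ground truth, plus
  rotation/scale/flip/elastic/noise augmentation — the package is testable
  end-to-end by parameter recovery.
* **Bookkeeping** (`split_dataset`, `write_mask`/`read_mask`, manifests,
  trait CSVs): deterministic largest-remainder 7:2:1 splits (optionally
  grouped by augmentation source), bit-exact label-mask PNG round-trips.
  A thin CLI lives at `inst/cli/stomatools`.

## Worked example

```r
library(stomatools)

# a synthetic 1600x1200 micrograph with exact ground truth
spec <- stoma_field_spec(n_stomata = c(19, 23))
s <- generate_sample(spec, seed = 42)
s
#> stoma_sample: 1200 x 1600 px, 19 objects, classes {0,1,2}

tr <- mask_to_traits(s$mask)
tr
#> image_traits: 19 stomata; mean length 117.0, width 67.1, area 6151.3
head(tr$records, 3)
#>   object_id length_px width_px area border_flag
#> 1         1  101.0000 64.00000 5109       FALSE
#> 2         2  133.2420 65.47678 6792       FALSE
#> 3         3  106.1815 80.50626 6661       FALSE

mean(s$objects$long_axis)   # generator ground truth: 116.7 px
mean(tr$records$length_px)  # recovered:              117.0 px

split_dataset(12600, c(7, 2, 1), seed = 1)
#> split_assignment (ungrouped): train 8820 / test 2520 / val 1260
```

The stoma count is recovered exactly (19/19), mean length within 0.3 px of
the generated ground truth, and the 7:2:1 split of 12,600 samples gives
exactly 8820/2520/1260. Training the tiny preset on 64 easy synthetic
128×128 fields for 30 epochs reaches held-out MIoU ≈ 0.93:

```r
easy <- stoma_field_spec(image_height = 128, image_width = 128,
                         n_stomata = c(2, 3), long_axis_range = c(36, 44),
                         short_axis_range = c(20, 26), pore_fraction = 0.45,
                         stoma_level = 210, pore_level = 40, noise_sd = 4,
                         noise_smooth = 2, margin = 2)
train <- lapply(1:64, function(i) generate_sample(easy, seed = 1000 + i))
val   <- lapply(1:8,  function(i) generate_sample(easy, seed = 9000 + i))
run <- train_model(build_model(model_config("tiny"), seed = 1), train, val,
                   train_config(initial_lr = 1e-3, epochs = 30, seed = 1))
tail(run$history$epochs$miou, 1)
#> 0.9301813
```

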