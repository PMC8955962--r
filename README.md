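# synquant

Machine-assisted quantification of immunological-synapse (IS) quality for
CAR-T cells imaged on glass-supported planar lipid bilayers.

## The problem

The quality of the immunological synapse a CAR-T cell forms against its
cognate antigen correlates with the cell's antitumor activity. On a planar
lipid bilayer the synapse is fixed in one imaging plane and recorded as a
five-channel confocal Z-stack: F-actin (channel 1, a peripheral ring),
perforin (2) and pZeta (4) clustering in the actin-sparse center, the
bilayer-presented tumor antigen (3), and DIC (5). Quantifying thousands of
synapses by hand is slow and irreproducible; `synquant` automates the
pipeline:

1. **Focal-slice selection** — the in-focus z is the slice maximising the
   per-slice mean intensity of the tumor-antigen channel.
2. **Cell detection** — keypoint-based bounding boxes: five keypoint
   classes per cell (four corners + center) with heatmaps and offset maps
   at four disk scales s1..s4; local heat maxima cast Hough votes
   `position + offset` for their object's center, votes agreeing at the
   accumulator-cell granularity form keypoint groups, any diagonal corner
   pair or any three keypoints construct a box, and greedy NMS removes
   duplicates.
3. **Instance segmentation** — each box is cut out with a context margin
   and segmented on the patch (a learned per-pixel classifier, or a
   deterministic Otsu threshold-oracle path); masks are decomposed into an
   ordered contour, a 1-px border and the interior.
4. **Quantification** — F-actin-derived masks are applied to channels 1-4
   at the focal slice to obtain each cell's total fluorescence intensity
   TFI = Σ gray values (border + interior parts reported separately).
5. **Statistics** — populations are compared per channel with the
   two-tailed pooled-variance t-test, histograms and empirical CDFs;
   detection/segmentation accuracy is scored as AP@t (area under the
   all-point precision-recall curve at IoU threshold t) and IOU@t (mean
   matched IoU), at t = 0.5 and 0.7, at box and mask level.

Because patient imagery is not distributable, the package ships a
synthetic-scene simulator (`generate_stack()`, `generate_dataset()`) that
renders the five-channel synapse layout with exact per-cell ground truth
(masks, boxes, injected per-channel signal), covering sparse to dense
populations, low-contrast boundaries, adhesion, impurity speckles and an
axial intensity profile peaked at a focal z. Everything downstream is
testable against it, with no data download.

## Worked example

```r
library(synquant)

p <- scene_params(n_cells = 5, adhesion_prob = 0, seed = 42)
scene <- generate_stack(p)

fp <- select_focal_slice(scene$stack)
fp
#> <focal_plane> z = 4 of 7 (channel 3)
#>   profile: 198.8 397.3 680.3 826.8 680.2 397.1 199.2

img <- stack_slice(scene$stack, 1, fp$z_index)   # F-actin focal slice
boxes <- detect_cells(img)                       # threshold-oracle path
instances <- segment_instances(img, boxes)

evaluate_instances(instances, scene$gt$masks)
#> <eval_result>
#>   box_ap@0.5 = 100.00%
#>   mask_ap@0.5 = 100.00%
#>   mask_iou@0.5 = 100.00%
#>   box_ap@0.7 = 100.00%
#>   mask_ap@0.7 = 100.00%
#>   mask_iou@0.7 = 100.00%

tfi <- per_cell_channel_table(scene$stack, fp, instances)
head(tfi, 4)
#>   image_id cell_id channel area_px      tfi border_intensity interior_intensity
#> 1  image_1       1       1     767 12177723          2224267            9953456
#> 2  image_1       1       2     767  2462304           194982            2267322
#> 3  image_1       1       3     767  6258198           105125            6153073
#> 4  image_1       1       4     767  1889612           151125            1738487

summarize_group(tfi$tfi[tfi$channel == 2])
#> <group_stats> n = 5, mean = 2189359.0 +/- 236294.8 (SEM), variance = 2.79e+11
```

The focal-plane profile recovers the generator's focal slice (z = 4); on
this well-separated noiseless-contrast scene the oracle path reproduces
every ground-truth mask exactly, so all accuracy metrics are 100%. Each
TFI row is one (cell, channel) measurement in raw integrated gray values,
with `tfi = border_intensity + interior_intensity` by construction.

A learned model replaces the oracle path after training:

```r
train <- generate_dataset(12, scene_params(n_cells = 4, adhesion_prob = 0), seed = 100)
model <- fit_synapse_model(train, train_config(learning_rate = 0.01, epochs = 6,
                                               scales = c(12, 24, 48, 96)))
instances <- predict(model, scene$stack)   # focal slice -> boxes -> masks
```

Published comparison scores of alternative architectures are bundled as
data and reduced with `compare_methods()`, e.g. the mean box-AP advantage
over the embedding-based baseline across all six data-fraction scenarios:

```r
compare_methods(method_table(), "InstSeg", "CosineEmbedding", method_cells("bbox"))$average
#> [1] 60.7
```

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from
scratch — simulating two cohorts that differ two-fold in perforin signal,
running focal-slice selection, detection, segmentation, quantification,
evaluation and the cross-cohort statistics — and writes a JSON report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Repository layout

- `R/` — simulator, I/O (TIFF/JSON/CSV), focal-plane selection, detection,
  segmentation, training/evaluation, quantification, statistics, pipeline,
  CLI.
- `tests/testthat/` — unit, property and acceptance suites (all fixtures
  generated in code).
- `vignettes/synapse-quantification.Rmd` — the methods vignette: model
  assumptions, parameter choices, numerical conventions, limitations.
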