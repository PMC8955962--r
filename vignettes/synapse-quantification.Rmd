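---
title: "Quantifying CAR-T immunological-synapse quality: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying CAR-T immunological-synapse quality: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synquant)
```

## The measurement model

A cytotoxic lymphocyte stimulated on a glass-supported planar lipid
bilayer forms its immunological synapse in a single optical plane. A
five-channel confocal Z-stack records, per channel: (1) F-actin, which
polymerises into a peripheral ring; (2) perforin, marking lytic
granules that polarise to the actin-sparse center; (3) the
bilayer-presented tumor antigen, accumulating centrally where the
receptor engages it; (4) phosphorylated CD3-zeta, the proximal
signalling mark, also central; and (5) DIC, a label-free transmitted
light image that is never quantified.

`synquant` turns such a stack into per-cell measurements in five steps.

**Focal slice.** The synapse sits where the antigen clusters, so the
in-focus slice is the z maximising the per-slice *mean* intensity of
channel 3 (`select_focal_slice()`). Whether the underlying notion of
"maximum intensity" is the slice mean, sum or maximum is genuinely
open; the mean was chosen because the per-slice sum is the mean times a
constant (identical argmax) while the per-slice maximum is dominated by
single impurity speckles and would make the choice non-robust. Ties
break to the lowest index for determinism.

**Detection.** Cells are located by keypoint voting at four disk scales
(radii 16, 32, 64, 128 px by default; the scale radii are not dictated
by any published value and simply bracket plausible cell sizes —
scale-matched synthetic cells are what the tests use). For each scale
and each of five keypoint classes (four box corners and the center) a
heatmap in [0, 1] and a two-channel offset map (horizontal and vertical
displacement toward the instance center) are produced. Local heat
maxima in a 3x3 neighbourhood above a fixed threshold of 0.1 cast Hough
votes at `position + offset`; votes whose voted centers agree at the
accumulator-cell granularity (transitively linked within a Chebyshev
distance of one cell, cell size = scale/4) form a keypoint group. A
group containing a diagonal corner pair spans a box directly; a group
of three or more keypoints including the center is solved by reflecting
known corners through the center to impute their diagonals, with
coordinates fixed by real corners taking precedence over imputed ones.
Box score is the mean confidence of contributing keypoints. Greedy NMS
at IoU 0.5 removes duplicate detections. Two readings of "votes landing
in the same accumulator cell" exist — hard grid binning versus
distance-based agreement at the cell granularity; grid binning splits
votes that straddle a cell edge arbitrarily (centers (15,15) and
(15,16) with cell size 8 would not group), so the distance reading is
used.

**Segmentation.** Each box is cropped with an 8 px context margin
(enough to include the full actin ring of a slightly under-tight box
while still excluding most of any neighbour) and segmented on the
patch; the largest connected component (8-connectivity throughout) is
kept. Masks are decomposed into an ordered outer contour (Moore
boundary tracing, completed so the contour pixel set equals mask minus
its 8-neighbourhood erosion), a 1-px border (pixels with any 8-neighbour
outside the mask; image edges count as outside) and the interior; the
border and interior partition the mask exactly. When several instances
claim a pixel, the highest-scoring instance wins; instances below 20 px
are dropped; whether predicted masks may overlap before reporting is
not externally fixed, so this score-based single-ownership rule is the
package's declared convention (it also mirrors how the ground truth is
defined: one owner per pixel).

**Quantification.** The F-actin-derived mask of each cell is applied
unchanged to channels 1-4 at the focal slice; TFI is the raw sum of
gray values under the mask, reported together with its border and
interior parts (`tfi = border + interior` is an identity, not an
estimate). No background subtraction or normalisation is applied by
default — the measurement is a masked sum of raw integers — and TFI is
computed on the single focal slice rather than a projection, consistent
with treating the bilayer plane as the synapse's plane of record.

**Statistics.** Populations are compared per channel with the
two-tailed pooled-variance Student t-test (`ttest_two_sided()`);
the description of the test as comparing two i.i.d. samples with
identical variances under the null matches the classical pooled test,
and Welch's correction is available behind a flag. Degenerate inputs
are defined rather than erroring: equal constant samples give t = 0,
p = 1; zero pooled variance with unequal means gives an infinite t and
a flagged p = 0 sentinel. Group summaries report n, mean, unbiased
variance and SEM; published per-channel intensity summaries of the form
"mean ± x" are interpreted as SEM (consistent with cohort sizes in the
thousands and the separately listed variances), which is an
interpretation, not a printed fact. Histograms use equal-width bins;
the ECDF is right-continuous, non-decreasing and ends at 1.

## Accuracy analysis

Detections are scored at box and mask level with AP@t and IOU@t at
t = 0.5 and 0.7. Matching is greedy and one-to-one: predictions in
descending score order, each taking the unmatched ground truth of
highest IoU if that IoU reaches t (ties to the lower index). AP is the
area under the all-point-interpolated precision-recall curve (the
PASCAL-2010 convention); the interpolation scheme is not externally
fixed, so it is isolated behind the evaluation configuration. IOU@t is
the mean IoU over matched pairs only: conditioning on matches is the
only reading under which IOU@0.7 can systematically exceed IOU@0.5 in
the published comparison table, which it does in every row. Comparison
arithmetic over such printed tables (`compare_methods()`) rounds
half-up to two decimals, reproducing printed pairwise deltas exactly;
two published segmentation-section averages (15.08 and 2.86) are
ambiguous about which columns they average (each is 0.01 off an exact
12-cell mean) and are deliberately not asserted anywhere.

## The learned model

No deep-learning framework is available to this package, and the
original backbone behind the keypoint heads is not disclosed; the
architecture is therefore a configuration choice behind a fixed
inference contract — keypoint maps in, boxes out; patches in, masks
out. The package's backbone is deliberately small: each head is a
one-hidden-layer MLP (16 tanh units) over 10 per-pixel features
(multi-scale Gaussian smoothings at sigma 1/2/4/8 of the [0, 1]-scaled
image, their difference-of-Gaussian band-passes, and gradient
magnitudes), trained with Adam (initial learning rate 1e-4 by default,
100 epochs, minibatch 1024) under random expansion, cropping, flipping,
contrast and brightness augmentation — geometric ops applied
identically to image and masks, photometric ops to the image only. The
detector head classifies F-actin foreground on the focal slice; its
thresholded connected components are converted to the five keypoint
heatmaps and offset maps per scale, and every box still flows through
the voting/grouping/construction/NMS chain. The segmenter head is
trained on per-instance patches in which neighbouring cells are
explicitly negative — the patch design exists precisely to stop
neighbour interference — and shares no weights or features with the
detector. Loss curves (binary cross-entropy) are recorded per epoch for
both heads, with validation losses when a validation split is supplied;
"epochs" and "iterations" are used interchangeably at this logging
granularity. Training is bit-reproducible from the config seed; all
randomness in the package flows from named substreams of one root seed.
Splitting follows floor/floor/remainder arithmetic after a seeded
shuffle, so 156 images yield 93/31/32 at 60/20/20.

A deterministic threshold-oracle path (Otsu threshold + largest
component) ships beside the learned path for both detection and
segmentation. It is not a fallback of convenience: on noiseless
synthetic scenes it recovers ground-truth masks *exactly*, giving the
entire downstream pipeline an exact, training-free reference against
which conservation and identity properties are asserted.

## The synthetic world

`generate_stack()` renders what the pipeline must cope with, not what
optics produce. Each cell is a radially Fourier-perturbed ellipse
(irregular but star-convex shapes); channel templates place a bright
F-actin ring at 85% of the cell radius over a dimmer actin base, 1-3
perforin/pZeta Gaussian clusters in the central 35%, a central antigen
accumulation scaled by `antigen_density`, and a DIC-like bright rim
over a mid-gray background. Per-channel gains (`channel_gains`) scale
channels 1-4 for cohort-level manipulations. The axial dimension is an
amplitude Gaussian in z centred on `focal_z` (width `axial_sigma`,
default 1.5 slices), reproducing a peaked slice-mean profile. Noise is
Gaussian read noise (default sd 0.4% of full scale) plus
signal-dependent shot-like noise plus sparse bright impurity speckles
placed on background only; masks are pairwise disjoint, adjacent only
through adhesion placements (probability `adhesion_prob`), and
non-adhering cells keep a >= 1 px gap. Defaults (192x192 px, 7 slices,
radii 10-18 px, 16-bit) are declared choices — pixel pitch, image size
and bit depth of the source microscope are nowhere specified, and
16-bit is simply the confocal convention.

Two deliberate departures from real optics matter for interpreting
green tests. First, every photon of a cell's signal is confined to its
ground-truth mask — there is no cross-boundary blur — which is what
makes the recorded per-cell injected signal exact and the noiseless
oracle identity achievable; real images leak signal across boundaries,
so exact-TFI tests certify the measurement arithmetic, not robustness
to optical spread. Second, the component-based conversion from
foreground to keypoint maps merges touching cells into one candidate
box, so heavily adhering scenes degrade detection in a way the original
deep keypoint regressor would not; tests that demand exact recovery
therefore use non-adhering scenes, and adhesion scenes are exercised
for geometry invariants (disjointness, partition) rather than accuracy.

## Numerical conventions

Coordinates are 0-based; boxes are half-open `[x_min, x_max) x
[y_min, y_max)`, so areas are exact side products and a pixel (x, y)
lives at matrix index (y+1, x+1). Focal-slice ties break low;
NMS suppresses at IoU >= threshold and is idempotent; AP of an empty
prediction set is 0 while AP without any ground truth is NA (an error
value distinct from 0); mean matched IoU without matches is 0 with a
warning. Otsu maximises between-class variance over a 256-bin
histogram. Serialized annotations use uncompressed column-major RLE
with `[x, y, w, h]` boxes; TIFF stacks are plain multi-page baseline
TIFF in channel-major (CZYX) page order with JSON metadata in the
ImageDescription tag, written and read by a self-contained codec (no
TIFF package exists in the dependency budget; the writer is
cross-checked against an independent Python reader in the tests).

## Limitations

Sub-slice focus interpolation, volumetric (multi-z) masks, overlap-aware
instance reporting, physically accurate point-spread simulation and
GPU-scale backbones are out of scope. Absolute accuracy values from the
original patient corpus are not reproducible here — they depend on
private data and full-scale training — so the package's accuracy claims
are confined to what its synthetic world can certify: exactness of the
oracle path, parameter recovery (e.g. a 2:1 injected intensity ratio
recovered within 10% at 50 cells per cohort), and calibration of the
statistical comparison under the null.
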