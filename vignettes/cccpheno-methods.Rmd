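---
title: "Methods: two-stage phenotyping of circulating cell clusters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-stage phenotyping of circulating cell clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cccpheno)
```

## The model

An imaging-flow-cytometry event is a co-registered triplet: a grayscale
brightfield image and two RGB fluorescence renderings — CD61 (platelet
marker, green) and CD45 (leukocyte marker, yellow). `cccpheno` implements a
two-stage decision chain over such triplets.

**Stage 1** decides cluster vs non-cluster from brightfield morphology.
The reference segmenter binarizes with Otsu's threshold (cells darker than
background, so the sub-threshold side is foreground), applies one
morphological opening then closing with a radius-2 disk, fills enclosed
holes, labels 4-connected components and drops those under 30 px. The
largest component is called a cluster when its area is at least 150 px and
it shows multi-cell structure: solidity (area over rasterized convex-hull
area) at most 0.92, **or** at least two interior minima. Minima are counted
two ways and the larger count wins: basins of the smoothed brightfield
intensity (cells are darkest at their centres) and basins of the
distance-to-background transform (two touching convex cells have two
distance peaks separated by a shallower neck). Both counts use threshold
decomposition — the maximum over levels of the number of connected
sub-level regions of at least 9 px with sufficient depth — which is an
h-minima criterion without an explicit morphological reconstruction.

**Stage 2** phenotypes records that pass stage 1. Each fluorescence channel
is converted to HSV — hue on the 0–179 half-degree scale, under which pure
green is 60 and pure yellow 30; `V = max(R,G,B)`; `S = 0` where `V = 0` —
and thresholded inside an inclusive box: green hue 35–85, yellow hue 20–40,
saturation 100–255, value `X`–255. `X` (default 140) is the tunable
fluorescence-brightness lower bound; the in-range stage is monotone in it,
so raising `X` only ever shrinks stain regions. One radius-1 opening
removes speckle. The overlap percentage of a stain mask `S` with the
cluster mask `M` is `100 |M ∩ S| / |M|` — the denominator is deliberately
the brightfield cluster area, not the union and not the stain area, so a
stain that covers the cluster and spills beyond it still scores 100. A
channel is *present* at overlap ≥ 15 % (inclusive), *artifact* when stain
exists but overlaps nothing, *absent* when overlap is positive but
sub-threshold, *no_stain* when the mask is empty. The decision table is
total: both present → WBC+platelet; green only → platelet; yellow only →
WBC; only-artifact evidence → excluded; anything else → RBC cluster.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `v_lo` (X) | 140 | 8-bit value | operating point selected by the brightness sweep; 100 admits noise, 170 starves the masks |
| `overlap_threshold_pct` | 15 | % of cluster area | balances sensitivity against spurious stain overlap; inclusive comparison |
| green hue | 35–85 | half-degrees | brackets green (60) from yellow-green to cyan-green |
| yellow hue | 20–40 | half-degrees | brackets yellow (30); overlaps green in 35–40 by design — a pixel may carry both calls |
| saturation | 100–255 | 8-bit | rejects grayish pixels |
| pad fill | (173,173,173) | RGB | neutral gray square padding before resize |
| input side | 224 | px | classifier input convention, bilinear |
| augmentation ×5 | 5 | copies/epoch | fixed-rate multi-augmentation emulating offline five-fold expansion |
| sweep grid | {100,140,170} × {5,8,10,13,15,18,20,30} | value × % | the explored operating-point grid |

Stage-1 rule constants (`min_component_area` 30 px, `min_cluster_area`
150 px, `max_solidity` 0.92, minima depth 2 intensity units at smoothing
radius 1) are package choices for the reference backend, selected on
held-out synthetic batches; they are not externally specified and a learned
backend plugged in through `register_backend()` bypasses them entirely.

## The synthetic world

The generator emulates the event taxonomy the pipeline must face: blank
fields, single cells, multiple separated cells (pairwise gaps of several
pixels), and touching/overlapping clusters; staining that covers the
cluster, partially covers it, or lies wholly outside it (debris artifact).
Concretely: shaded dark ellipses (base intensity U[40,120], rising by 30 at
the rim, radii 8–14 px in a 96 px frame, axis ratio 0.7–1) on a bright
background (level 200, Gaussian noise sd 5 by default); consecutive cluster
cells sit at centre distance `0.75 (r_i + r_j)`; separated cells keep a
gap of at least 6 px — comfortably inside the "≥ 3 px" contract — so that
rasterization plus radius-2 closing can never bridge them. Stain is painted
as a coherent region of exactly `round(coverage × area)` mask pixels at
HSV (60 or 30, 220, intensity 200); artifacts as blobs at least 2 px
outside the mask. Every record is deterministic given its seed.

What the generator does **not** emulate: point-spread blur, spectral
bleed-through between channels, intensity gradients across the field,
debris that touches the cluster, and partial-volume boundary pixels. A
green test therefore establishes that the decision logic and its
thresholds behave as specified on well-posed inputs — not that the
classical reference segmenter matches a trained detector on clinical
images.

## Numerical choices

* **Hue dialect.** The printed channel ranges (green 35–85, yellow 20–40)
  are only consistent with the half-degree 0–179 hue scale; the package
  fixes that dialect and documents it in `rgb_to_hsv255()`.
* **Inclusive bounds** at both ends of every HSV box, and an inclusive
  `≥` at the overlap threshold.
* **Polygon convention.** Contours are traced on the pixel-corner lattice
  (the exact outline of the union of pixel squares), normalized as
  x = column/width, y = row/height, counter-clockwise by positive
  shoelace area. Rasterization marks a pixel when its centre is inside
  (even–odd rule) or within 1e-9 of an edge; a zero-area polygon
  rasterizes empty. The mask → polygon → mask round trip is bit-exact for
  a hole-free 4-connected component, and ≥ 0.98 IoU is guaranteed for
  convex regions.
* **Padding ties** put the extra pixel on the right/bottom.
* **AP interpolation.** 101-point interpolation (the mAP@0.5:0.95
  convention); the test oracle integrates the all-point envelope instead,
  and the two agree within 0.01 on small detection sets.
* **Ties.** Equal-area instances order by lower top-left raster index;
  equal detection confidences keep input order.
* **Degenerate inputs.** A constant image yields an empty segmentation
  (Otsu undefined); an empty cluster mask makes the overlap percentage an
  error rather than a silent 0; zero metric denominators return 0 with a
  warning.

## Open design points and how they were resolved

* **The RBC / excluded boundary.** The no-stain case is not externally
  pinned down. Here: a record is *excluded* only when its sole stain
  evidence lies wholly outside the contour; when no channel has stain, or
  all overlaps are positive but sub-threshold, it is an RBC cluster (a
  cluster of cells the two markers do not stain). This is the module's
  most consequential interpretation and is centralized in
  `phenotype_from_states()`.
* **Mixed evidence is not an artifact.** A channel with some overlap plus
  a large outside area proceeds to classification.
* **Overlap against which instance?** The largest segmented instance, one
  region of interest per record.
* **Stage disagreement** (classifier says cluster, segmenter finds
  nothing) is flagged on the record, never guessed away.
* **Sweep scoring.** Records whose ground truth is *excluded* are dropped
  before sweep accuracy by default (`artifact_mode = "exclude"`), matching
  the practice of removing artifact images before phenotype scoring; an
  `as_class` mode keeps them as a fifth class.
* **Fold construction** is stratified with seeded shuffling; remainders go
  to the lowest-index folds, which reproduces the published per-fold
  test-set totals (314, 314, 314, 313, 313 over 1,568 records) exactly,
  while per-class fold counts are seed-dependent.
* **File formats.** PNG only (8-bit, via the `png` codec); proprietary
  cytometer containers and TIFF are out of scope in this environment.

## Known limitations

The stage-1 reference rule reaches ~96–99 % agreement with ground truth on
synthetic batches but cannot reach 100 %: a compact cluster of heavily
overlapping, similar-intensity cells is genuinely indistinguishable from a
single blob without learned texture cues — exactly the gap the original
learned classifier fills. End-to-end recovery claims in the tests are
therefore stated for the stage-2 phenotyping path (segmentation mask →
stain overlap → label), which is the part of the pipeline this package
contributes in full. Deep-model training, SAM-assisted annotation, and
clinical-image benchmarks are out of scope.
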