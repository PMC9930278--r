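---
title: "Counting Grande and Petite colonies: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting Grande and Petite colonies: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colonyscan)
```

## The assay

Baker's yeast cells that lose mitochondrial respiration form *Petite*
colonies: on media with limited glucose and a non-fermentable carbon
source they stay small and translucent, while respiring *Grande* colonies
grow large and dense. The fraction of Petites on a plate — the Petite
frequency `P` — is a standard readout of mitochondrial DNA integrity, and
measuring it means counting hundreds of colonies per dish across many
dishes. `colonyscan` automates that count from flatbed scans of single
petri dishes and attaches the statistical context needed to interpret the
result: if Petite formation is a Bernoulli process, a plate of `k`
colonies measures `P` with standard deviation `sqrt(P * (1 - P) / k)`, so
any detector whose error is small against this envelope is statistically
interchangeable with manual counting.

## The classical detector

`detect_colonies()` composes five stages, each exposed on its own:

1. **Plate localization** (`locate_plate`): a circular Hough transform on
   the Sobel edge map, radii swept over 0.30–0.49 of the smaller image
   dimension (run on a copy downsampled to ~256 px for speed; the
   accumulator cell size at that scale is well inside the tolerance any
   downstream stage needs). A blank or plate-free image falls back to the
   inscribed circle with a warning rather than an error, so batch runs
   continue.
2. **Segmentation** (`segment_colonies`): the image is masked to the
   plate disc shrunk by `rim_margin` (default 3% of the radius, excluding
   the rim refraction zone), thresholded, and split into colonies by
   watershed on the distance transform.
3. **Feature extraction** (`extract_features`): per region, pixel-count
   area, best-fit-ellipse eccentricity and mean intensity.
4. **Filtering** (`filter_regions`): area within [40, 6000] px² (bounds
   inclusive) and eccentricity below 0.9. The area bounds assume roughly
   600-DPI single-dish scans (≈2376 × 2288 px); the eccentricity cut
   removes arc-shaped refraction artifacts, which are nearly
   one-dimensional.
5. **Classification** (`classify_regions`): colony size and brightness
   are the two phenotypically meaningful features, so regions are
   standardized on (area, mean intensity) and cut into two groups by
   average-linkage agglomerative clustering; the cluster with the larger
   mean area is Grande. With fewer than four regions, or when either
   feature is constant, a plain 1000 px² size threshold takes over.

Classical detections carry score 1.0: the pipeline has no calibrated
confidence, and a nominal lower score would silently fall below the
merging stage's 0.6 eligibility floor.

### Why multi-level Otsu

Otsu's method picks the threshold maximizing between-class variance. With
two classes it is driven by pixel mass, and Petite colonies contribute
almost none: on a typical plate the agar holds ~90% of the masked pixels
and Grande colonies nearly all the rest, so the two-class threshold
settles between agar and *Grande* intensity — above the Petite peaks —
and the translucent Petites vanish into the background. This is precisely
the known failure mode of semi-supervised colony detectors on faint
colonies. `segment_colonies` therefore computes a three-class Otsu
partition (background / faint / bright, an exhaustive search over 256²
threshold pairs) and uses the *lowest* threshold as the foreground cut.
To keep a blank plate from being shredded into noise speckle, that cut
must also clear a robust noise floor (median + 6 × MAD of the masked
pixels); if no threshold does, the foreground is empty and zero regions
are returned — never an error.

### Watershed details

Touching colonies are split by marker-based watershed on the negated
distance transform. The marker neighbourhood radius follows the smallest
admissible colony scale, `0.8 * sqrt(min_area / pi)` (≈3 px at the
default 40 px² minimum), with a merge tolerance of 1 px of distance-map
depth so the ragged, noise-perturbed outline of a single colony does not
fragment. Labels are contiguous from 1; connectivity follows the
watershed labeling.

## Sliced inference and non-maximal merging

Small objects vanish when large images are fed to detectors at reduced
resolution, so the package also provides sliced inference
(`infer_sliced`): square windows of side `S` with fractional overlap
(default 0.2) are run through a pluggable backend, and the window-local
detections are merged globally. The slice side comes from the image-area
equation `S = sqrt(I_w * I_H * S_A)` with `S_A` defaulting to
`(512 * 512) / (2376 * 2288)` — an image at that reference resolution
yields 512 px slices, and rescaled images keep the colony-to-slice size
ratio constant. When colony sizes differ grossly from those conventions,
the alternative `S = (GD_I / GD_t) * 512` pins the ratio through a typical
Grande diameter instead; `GD_t = 60` px is a recorded constant of this
package, not a measured property of any external dataset, and should be
treated as user-supplied. Boundary windows are shifted back inside the
image rather than padded, because padding would synthesize dark borders no
backend was designed for.

A backend is any function `(region, window) -> detections` in
region-local coordinates; `classical_backend()` adapts the classical
stages (minus plate localization, which is meaningless on a slice), and
`oracle_backend()` replays ground truth for validating the machinery.

Duplicate detections from overlapping windows are fused by **non-maximal
merging** (`nmm`): detections below the 0.6 confidence floor are dropped,
and same-class detections overlapping by more than 0.5 *intersection over
smaller area* are merged into their coordinate-union box carrying the
maximum member score. IOS rather than IOU is essential here: a fragment
of a colony clipped at a window edge is nested inside the full detection
from a neighbouring window, giving IOS 1 but possibly a small IOU.

Merging is defined as connected-component closure: each pass fuses the
connected components of the pairwise eligibility graph (evaluated on the
pass-input boxes), and passes repeat until no same-class pair in the
output exceeds the threshold. The naive alternative — merging one
eligible pair at a time and re-testing against the grown union box — is
order-dependent whenever a "bridge" box overlaps two clusters that do not
overlap each other, so its output would depend on scan order; the
component semantics is order-independent, idempotent, and is what the
test suite pins against an independent Floyd–Warshall closure oracle.
The score floor is applied before merging (an eligibility floor), so
sub-threshold detections are dropped rather than merged, and the floor
also defines the final reported set.

## The synthetic plate generator

Every stage is testable without real scans through `simulate_plate()` /
`simulate_batch()`, which emulate the assay's imaging conditions with
exact ground truth:

* dark background (mean 10/255, the black-felt backing of a flatbed
  scanner) against a lighter agar disc (mean 90/255), dish radius 0.46 of
  the smaller image dimension, frame 2376 × 2288 px — the pixel scales of
  a 600-DPI single-dish crop;
* a Poisson number of colonies (mean 78 per plate), each independently
  Petite with probability `petite_prob`; Grande radii 18–44 px with peak
  intensity ~220, Petite radii 4–12 px with peak ~140 ("smaller and more
  translucent"); the 4–44 px span matches the radius range the area
  filter bounds were derived from, and the non-overlapping class ranges
  are the premise the size-based classifier exploits;
* colony blobs with a plateau-plus-Gaussian-falloff radial profile
  (plateau to 0.7 R, falloff scale 0.25 R) — soft edges, so thresholding
  behaves as on real scans; hard discs would make segmentation
  unrealistically easy;
* a configurable fraction of colonies (default 10%) placed as
  deliberately touching same-class pairs, discs overlapping by 20–50% of
  the smaller radius, to exercise watershed splitting;
* colonies are kept inside 97% of the dish radius (the meniscus and rim
  refraction zone of real plates), with a 2 px clearance between
  non-pair colonies; placement is rejection-sampled and an infeasible
  packing raises an error after a bounded number of attempts;
* `mode = "diffuse"` blurs the colony layer with sigma 0.3 × the mean
  Petite radius, a stand-in for low-quality diffuse agar — a tunable, not
  a claim about real media; optional thin bright arcs just inside the rim
  (eccentricity near 1 by construction) emulate refraction from
  neighbouring dishes; additive Gaussian noise (sigma 3/255) tops off the
  scene;
* ground-truth boxes are the tight boxes of each colony's *rendered*
  footprint thresholded at `agar_level + 3 * noise_sigma` — what an
  annotator would draw on the image, not the generating disc.

Everything derives from one integer seed (plate `i` of a batch uses
`seed + i`), and identical configurations are bit-identical. What the
generator does **not** model: agar texture, colony pigment, uneven
illumination, condensation, multi-dish composite scans, or cross-class
touching pairs. Passing tests on synthetic plates therefore demonstrate
the correctness of the machinery and the self-consistency of the
pipeline, not field performance on real scans.

`downscale_plate()` supports resolution-robustness experiments: bilinear
resize to `round(dim * factor)` with a Gaussian antialiasing pre-blur of
sigma `(1/factor - 1) / 2`, the standard minification treatment, so
sub-pixel colonies are averaged away rather than aliased.

## Evaluation

`match_detections()` performs the usual greedy one-to-one matching per
class: detections in descending score order claim the unmatched ground
truth with the highest IOU at or above the threshold. `average_precision`
uses the COCO conventions — monotone (ceiling) interpolation of precision
and a 101-point recall grid — because the report aggregates
mAP@[0.5:0.95] in COCO style; since the interpolated precision envelope
is monotone with total variation at most 1, the 101-point sum is within
0.01 of exact integration, which the suite checks against a brute-force
oracle. `map_report()` computes AP per class over IOU 0.50–0.95 in 0.05
steps, with per-class precision/recall at 0.5 and no score cut by default
(a cut is a caller decision). `resolution_sweep()` ties the pieces
together: downscale, redetect, score, and report per-class
precision/recall plus the mean absolute Petite-frequency error per scale
factor.

On synthetic sweeps the Petite recall collapses at a larger scale factor
than the Grande recall, as expected from their pixel budgets. One known
limitation: at 0.1 of the default resolution the largest Grandes
(radius ≈ 44 px, so ≈9 px across after scaling) still exceed the fixed
40 px² minimum-area filter and a small residue of Grande detections
survives (~2% recall), whereas learned detectors at that scale lose all
colonies; a fixed-parameter classical detector degrades differently than
a CNN.

## Numerical choices and degenerate inputs

* Boxes are half-open, 0-based, real-valued; rasterization happens only
  at rendering/export. Intersection arithmetic is exact for integer
  boxes.
* Slice sizes round to the nearest pixel and clamp to
  [32, min(I_w, I_H)]; an image smaller than one slice degenerates to
  whole-image inference.
* A plate with no colonies yields an *NA* frequency (CSV `NA`), never
  0/0; empty foregrounds, empty detection lists and empty COCO
  annotation arrays are all legal values, not errors.
* Average-linkage merge order follows `stats::hclust` on rows pre-sorted
  by region id, so classification is invariant to caller row order; the
  Grande/Petite labeling of clusters uses mean area (size is the primary
  phenotype; intensity is secondary).
* Class names are a closed set (`grande`, `petite`, lower case in all
  serialized forms); unknown names in input files are hard errors, since
  the frequency is defined only over these two.
* The COCO dialect (category ids 1/2, `score` extension field) is this
  package's own and is documented in `read_coco()`/`write_coco()`.

## Problem sizes in the test suite

The shipped tests exercise full-scale plates (2376 × 2288 px, ~100
colonies) for the end-to-end recovery and resolution-sweep checks — 20
and 4 plates respectively — and 700 × 680 px plates elsewhere; oracle
equivalence checks run on hundreds of small random instances. These sizes
were chosen to give stable statistics for the stochastic assertions
(pooled counts of several hundred colonies per class) while keeping the
suite comfortably runnable on a laptop.
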