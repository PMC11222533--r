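---
title: "Prompt-engineered segmentation and capillarization assessment: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prompt-engineered segmentation and capillarization assessment: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capquant)
```

## The measurement problem

Single immunostaining of a basement-membrane protein (collagen IV) labels
cardiomyocytes (CMs) and capillaries simultaneously: both appear as dark
interiors enclosed by bright membrane ridges in a single fluorescence
channel. Quantitative capillarization assessment then needs every CM and
capillary *instance* identified, classified, and segmented. `capquant`
implements a weakly supervised pipeline for this: an object detector
(trainable from bounding boxes alone) supplies classified detections; a
prompt generator converts each detection into an engineered prompt; a
promptable segmentation backend turns each prompt into one mask; and the
seven capillarization measurements are derived from the masks.

## The prompt model

Each detection $i$ contributes a box $B_i$ and its geometric centre
$c_i$. The prompt for $i$ is the pair $(B_i, P_i)$ with

$$P_i = \{\, (c_j, \mathbf{1}[j = i]) \;:\; c_j \in B_i \,\},$$

built by traversing all $n$ detected centroids, an $O(n^2)$ operation.
$B_i$ is the *coarse* constraint — no predicted pixel may fall outside it,
and it carries the class label — while $P_i$ is the *fine* constraint: the
target's own centroid is a positive (label-1) point, and every foreign
centroid that intrudes into $B_i$ is a negative (label-0) point.

The fine constraint exists because myocardial cross-sections are densely
packed: CM profiles are non-convex, so boxes of adjacent CMs overlap
routinely, and small capillary boxes frequently sit entirely inside a CM
box. With box-only prompts a segmenter has no way to know which of several
structures inside the box is meant; the labeled centroids disambiguate.

Decisions taken where the design was genuinely open:

* **Centroids are box centres**, not mask centres of mass. At inference
  only detections exist — there are no masks to take moments of — so the
  prompt generator must work from boxes alone. A box always contains its
  own centre, which guarantees each prompt exactly one positive point.
* **Half-open membership.** Boxes are 0-based, half-open
  ($[x_{\min}, x_{\max}) \times [y_{\min}, y_{\max})$), matching COCO
  raster indexing and making area = width × height exact. A centroid lying
  exactly on a box's upper edge is *outside*; ties are thereby decided
  deterministically. Whether the original formulation included such
  edge-touching centroids is unknowable from its description; any rule
  change affects only measure-zero configurations.
* **Duplicates are not special.** Identical detections each get their own
  prompt and see the twin's centroid as a negative point; deduplication is
  the detector adapter's concern (e.g. non-maximum suppression), not the
  prompt engine's.
* **No cap on negative points.**

## Detector and segmenter contracts

The package's contribution is the prompting and measurement machinery, so
both neural components are adapter slots behind registries:

* `detect()` dispatches to a registered adapter and enforces the shared
  contract (confidence filtering, in-frame clipping, stable sort by
  descending confidence with $x_{\min}$, $y_{\min}$ tie-breaks). The
  shipped **oracle detector** emits one detection per ground-truth mask —
  tight box via circumscription, label copied, confidence 1 — with
  optional seeded uniform jitter of $\pm j$ px per edge to emulate an
  imperfect detector. This decouples every downstream test from any
  trained model.
* `segment_with_prompts()` runs a registered backend once per prompt and
  **clips every mask to its prompt box** afterwards, because external
  promptable models do not themselves guarantee the coarse-constraint
  semantics. One mask per prompt; a backend that finds nothing yields an
  empty mask flagged as a failed prediction, not an error. How a
  multi-proposal backend should reduce its proposals to one mask is left
  to the adapter.

The **reference segmenter** makes the pipeline runnable with no weights:
crop to the box, Otsu-threshold within the crop, keep the dark phase
(basement-membrane polarity: bright ridges, dark lumens/cytoplasm), label
4-connected components, return the component under the positive point,
and delete any component containing a negative point. The deletion rule is
applied literally: if a negative point lands in the *same* component as
the positive point, that component is deleted too and the prediction
fails. This keeps the invariant that an output mask never contains a
negative point — the conservative reading of the fine constraint — at the
cost of occasionally dropping a true object when two structures' dark
phases merge.

## Evaluation scheme

Matched prediction–truth pairs are classified at IoU threshold $\phi$ by a
four-way rule: same label and IoU $\ge \phi$ → TP; same label, IoU
$< \phi$ → FP; different label, IoU $\ge \phi$ → TN; different label, IoU
$< \phi$ → FN. The TN cell for label-mismatched high-IoU pairs departs
from strict COCO convention; it is implemented verbatim as the package's
default because it is the scheme the measurements are defined under, with
a strict-COCO mode behind `rule = "coco"` for comparability. Precision
and recall use TP/FP/FN only; TN is tallied and reported.

Matching itself is unspecified in the scheme's description, so the package
fixes **greedy one-to-one matching by descending IoU, label-agnostic**,
with unmatched predictions as FP and unmatched truths as FN. On
unambiguous scenes (each prediction overlapping a single truth) greedy
matching provably coincides with exhaustive optimal assignment, and the
test suite checks that equivalence by enumeration on small scenes.

Metrics come in three settings: single thresholds 0.5 and 0.75, and the
sweep $\{0.50, 0.55, \ldots, 0.95\}$ under which mAP/mAR are additionally
averaged over the ten thresholds. AP uses 101-point score-ranked
interpolation when every prediction carries a confidence score; when a
backend emits no scores (the reference segmenter does not), AP falls back
to set-level precision at the operating point and the report records
which mode was used. mAP/mAR average over the class labels present in the
ground truth; F1 is their harmonic mean, matching the convention of
presenting a single F1 beside mAP/mAR. Plain accuracy is provided only as
a diagnostic: with 9 capillaries and one missed CM it reads 90% while CM
performance is zero, which is exactly why it is excluded from headline
metrics. Repeated test runs aggregate as mean ± sample SD ($n-1$), five
runs by default.

## Capillarization measurements

From one image's labeled masks: $n_{CM}$, $n_{CAP}$, total CM and
capillary areas in μm² (pixel count × per-axis pixel size from the image
metadata; 512 × 512 px over a 42.5 μm square FOV gives 1806.25 μm² per
frame), CDFA $= n_{CAP} / \text{FOV area}$, CDCA $= n_{CAP} /
\text{CM area}$, CCR $= n_{CAP} / n_{CM}$. Three identities hold exactly
by construction and are asserted property-style in the tests:
CDFA · FOV area $= n_{CAP}$; CDCA · CM area $= n_{CAP}$ (when CM area
> 0); CCR · $n_{CM} = n_{CAP}$ (when $n_{CM} > 0$). Undefined ratios
(no CM) propagate as explicit `NA` flags, never silent zeros. Whether
"total area" should sum per-mask areas or the union of possibly
overlapping predictions is ambiguous for predicted masks; the default
sums per mask, with `area_mode = "union"` available. CDFA divides by the
physical FOV area, not the annotated-structure area. Relative error per
measurement is $\delta = |p - t| / t$, undefined at $t = 0$ and flagged.

## Dataset tooling

* **Preprocessing**: 3 × 3 adaptive Wiener filtering then a linear
  percentile contrast stretch (0.35% / 99.65% clipping) to full dynamic
  range. The Wiener step is the standard pixelwise local mean/variance
  estimator with noise power estimated as the mean local variance;
  replicate padding makes a constant image a fixed point. The stretch
  percentiles are a package choice — the named workflow's enhancement
  method is unspecified — and the mapping is monotone by construction.
* **Splits**: test fraction 0.30 of all items, then 0.10 of the remainder
  for validation, both with round-half-up. This rounding is the unique
  simple rule reproducing the documented 67/8/32 partition of 107 images.
  Shuffles are seeded and the seed is recorded in the manifest.
* **Rotation augmentation** emits all three fixed directions (90° cw,
  90° ccw, 180°) per image — a deterministic superset of "random
  rotation" — and `augment_dataset(target_total =)` draws a seeded
  subsample when a specific augmented count is wanted, since the original
  67 → 209 expansion is not fully specified by its description.
* **Mosaic augmentation** downscales four samples by 2 (block mean for
  images, odd-index subsampling for masks, which is label-preserving) into
  the four quadrants, with seeded quadrant assignment. Subsampling maps a
  box $[z_{\min}, z_{\max})$ to $[\lceil z_{\min}/2 \rceil,
  \lfloor (z_{\max}-1)/2 \rfloor + 1)$; masks thinner than 2 px can vanish
  and raise an error rather than emit empty instances.
* **Formats**: COCO JSON (uncompressed RLE written; RLE and polygon read,
  polygons via even-odd scanline fill on pixel centres), COCO detection
  JSON, YOLO-txt (normalized, 6 decimals — half-pixel round-trip), 16-bit
  TIFF, and labeled instance-index TIFF with a JSON label sidecar.
* The ROI admission criterion (≥ 80% of the FOV covered by annotated
  myocardial structures) is available as `roi_admissible()`.

## The synthetic scene generator

Real basement-membrane image data cannot ship with the package, so every
closed-loop test runs on seeded synthetic scenes designed to reproduce the
*geometric* phenomena that motivate the prompt design, not photorealism.

A scene is a warped-distance tessellation: each of $n_{CM}$ cells has a
seed point and an angular radial warp
$w(\theta) = 1 + \eta\,(a_1 \cos(k_1\theta + \varphi_1) + a_2 \cos(k_2
\theta + \varphi_2))/2$ with irregularity $\eta \in [0,1]$; pixels join
the cell minimizing $r / w(\theta)$. Rising $\eta$ produces the lobed,
interlocking profiles that make CM boxes overlap. Interiors are separated
by eroding each cell region (zero-padded first, so the frame edge erodes
like any cell boundary); ring-shaped capillaries — dark lumen inside a
bright ring — are wedged at tessellation boundary sites with separation
margins, their footprints carved out of CM interiors so ground truth is
pairwise disjoint by construction. Rendering follows staining polarity
(bright ridges ~75% of dynamic range, dark interiors ~12%) plus Gaussian
noise, quantized to the metadata's bit depth.

Defaults: 512 × 512 px, 42.5 μm square FOV, 16-bit — the standard
acquisition geometry — with 6 CMs, 2 capillaries per CM, erosion depth
2 px, noise SD 800 counts, lumen radii 3.5–5.5% of the frame side
(≈ 1.5–2.3 μm at 512 px, a realistic capillary lumen). The `"easy"`
preset ($\eta = 0.2$, no noise) is the clean benchmark setting; the
`"default"` preset ($\eta = 0.6$, noisy) is the dense regime in which, in
practice, every capillary box is enclosed by a CM box and most CM box
pairs overlap, so fine constraints are genuinely exercised.

What passing closed-loop tests on these scenes shows: the prompt
machinery, constraint semantics, evaluation, and measurement arithmetic
are correct end to end under the stated packing phenomena. What it does
not show: performance on real immunofluorescence — synthetic membranes
have uniform brightness and closed contours, no staining dropout, no
out-of-focus light, no autofluorescence channel, and the reference
segmenter's Otsu step is far cruder than a learned promptable model.
Benchmark numbers on synthetic scenes are therefore properties of the
pipeline, not claims about tissue.

## Numerical choices and degenerate inputs

* IoU of two empty masks is an error (union empty), and an all-empty
  prediction scores IoU 0 against any non-empty truth.
* `bbox_from_mask` on an empty mask errors rather than returning a
  degenerate box; box constructors reject zero extent.
* Otsu within a structureless (constant) crop, or a positive point landing
  on the bright phase, yields a failed prediction, not an exception.
* Fractional (jittered) boxes clip to the pixel grid by including
  fractionally covered pixels; jittered boxes keep ≥ 1 px extent and stay
  in frame.
* Splits error when any partition would be empty; run aggregation errors
  below 2 runs; relative error errors at zero truth.
* Determinism: scenes, jitter, shuffles, and mosaics are functions of
  `(spec, seed)`; the reference segmenter and evaluation are
  deterministic, so fixed seeds reproduce the whole pipeline bit-for-bit.

## Problem sizes

Closed-loop tests use 96–160 px rasters (the generator's geometry is
scale-free; the standard FOV is kept so physical units stay realistic),
and the reproduction script `scripts/acceptance.R` runs five test runs of
two 128 px scenes under the IoU-0.5 and sweep settings, clean and under
4 px box jitter — sizes chosen so the whole suite re-runs in well under a
minute while every phenomenon of interest (box overlap, capillary
enclosure, jitter degradation) still occurs.

## Known limitations

* The reference segmenter assumes bright-boundary/dark-interior polarity
  and a bimodal crop histogram; it is a contract-faithful stand-in for a
  promptable model, not a competitor to one.
* Box-centre positive points can miss strongly non-convex cell interiors
  (the centroid lands on or beyond a ridge), producing failed predictions
  at high irregularity — visible in the README's worked example.
* The four-way outcome rule's TN cell makes cross-method comparisons with
  strict-COCO numbers inexact; use `rule = "coco"` for those.
* No rotated boxes, no sub-pixel masks, no 3-D (Z-stack) assessment, no
  multi-channel handling, no stain normalization.
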