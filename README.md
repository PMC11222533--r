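# capquant

Prompt-engineered instance segmentation and capillarization assessment for
basement-membrane-immunostained myocardium.

## The problem

Cardiac capillary rarefaction — a drop in capillary density around
cardiomyocytes (CMs) — accompanies many heart disorders. Quantifying it
from tissue sections usually requires double immunostaining (one marker
for CMs, one for vessels). Single immunostaining of a basement-membrane
protein such as collagen IV is far easier at the bench: one stain outlines
*both* CMs and capillaries as bright ridges around dark interiors. The
price is paid at analysis time, because telling a CM profile from a
capillary ring in a single channel takes expertise and manual work.

`capquant` implements a weakly supervised route around that: an object
detector (trained on cheap bounding-box annotations only) finds and
classifies objects, an engineered prompt is built for each detection, and
a pluggable promptable segmenter turns each prompt into a pixel mask —
no pixel-wise training labels needed. Capillarization statistics are then
derived from the masks.

## The core algorithm: enhanced prompts for dense tissue

For each detected object *i*, the prompt has two parts:

* **Coarse constraint** — the bounding box *B<sub>i</sub>*, which caps the
  maximal extent of the predicted mask and carries the class label.
* **Fine constraint** — a binary-labeled point set
  *P<sub>i</sub>* = { (*c<sub>j</sub>*, 1) if *j* = *i*, else
  (*c<sub>j</sub>*, 0) : *c<sub>j</sub>* ∈ *B<sub>i</sub>* },
  built by traversing the centroids of *all* detections and keeping those
  that fall inside *B<sub>i</sub>* (cost O(n²) in the number of
  detections).

In myocardium the fine constraint is not optional: CM profiles are
non-convex and tightly packed, so their boxes overlap, and capillary boxes
are frequently *fully enclosed* by CM boxes. A box-only prompt then bleeds
into neighbours; the negative centroids tell the segmenter what to
exclude.

From the final masks the package computes, per image: CM count, capillary
count, total CM and capillary areas (μm²), **CDFA** (capillaries per FOV
area, μm⁻²), **CDCA** (capillaries per CM area, μm⁻²), and **CCR**
(capillary-to-CM ratio), plus relative errors δ = |predicted − truth| /
truth against ground truth.

Everything runs without any pretrained weights: a ground-truth-backed
oracle detector (with optional seeded box jitter) and a deterministic
reference segmenter (Otsu within the box crop, dark-object polarity,
connected components gated by the prompt points) close the loop on
synthetic scenes from the built-in generator. Real detectors and
promptable models plug in through `register_detector()` /
`register_segmenter()`.

## Worked example

```r
library(capquant)

meta  <- image_meta(256, 256, fov_um = 42.5)      # 42.5 um square FOV
scene <- generate_scene(scene_preset("default", meta = meta, seed = 42))
scene_statistics(scene$masks)
#> $n_cm                  [1] 6
#> $n_cap                 [1] 12
#> $cap_enclosed_fraction [1] 1      # every CAP box sits inside a CM box
#> $cm_box_overlap_rate   [1] 0.8    # 80% of CM box pairs overlap

cfg    <- pipeline_config(detector = detector_config(annotations = scene$masks),
                          meta = meta)
result <- predict_instances(scene$image, cfg)
result
#> <segmentation_result> 18 mask(s) from backend 'reference' (1 failed)

evaluate_instances(list(result), list(scene$masks), eval_config("iou50"))
#> <eval_report> setting iou50 (1 threshold, AP set-level)
#>   mAP 0.917  mAR 0.917  F1 0.917

report <- assess(result$instances[!result$failed], meta)
report
#> <capillarization_report>
#>   CMs: 5 (1178.0 um^2)   capillaries: 12 (140.8 um^2)
#>   CDFA 0.006644 um^-2   CDCA 0.01019 um^-2   CCR   2.4

report_errors(report, assess(scene$masks, meta))
#>    measurement    predicted        truth     delta defined
#> 1         n_cm 5.000000e+00 6.000000e+00 0.1666667    TRUE
#> 2        n_cap 1.200000e+01 1.200000e+01 0.0000000    TRUE
#> ...
```

Reading it: the default (noisy, strongly lobed) preset packs 6 CMs and 12
capillaries into the frame. One CM prediction fails — its box centroid
lands on a membrane ridge, a known failure mode of centroid prompts on
non-convex cells — so counts, areas and the derived densities for CMs are
off by one cell (δ between 0.17 and 0.22), while every capillary
measurement is exact. At IoU 0.5 the scene scores mAP = mAR = F1 = 0.917.

## Command line

A thin CLI over the same functions ships in `inst/cli/`:

```sh
capquant synth --preset easy --size 256 --seed 1 --out scene/
capquant predict --input scene/scene.tif --gt scene/ground_truth.json --size 256 --out pred/
capquant assess --gt pred/predicted.json --size 256 --out pred/
capquant evaluate --gt scene/ground_truth.json --pred pred/predicted.json --out eval/
capquant benchmark --runs 5 --images 3 --size 256 --out bench/
```

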