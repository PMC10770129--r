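---
title: "Detecting tertiary lymphoid structures in H&E slides: models and methods"
author: "tlsdetect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting tertiary lymphoid structures in H&E slides: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the model and its
assumptions, the parameters that matter, what the synthetic data does and
does not emulate, the numerical choices, and the design decisions taken
where the design was genuinely open. Code chunks are illustrative and not
evaluated at build time; the quantitative statements below are exactly the
ones computed by the test suite and by `scripts/acceptance.R`, and nothing
more.

## 1. The problem

Tertiary lymphoid structures (TLS) are dense, sharply contoured aggregates
of lymphocytes that form in chronically inflamed tissue; mature TLSs
develop a paler germinal center (GC) of proliferating blasts. On routine
H&E slides they must be told apart from diffuse inflammatory infiltrates
(no distinguishable contour) and from true lymph nodes (the same tissue in
its orthotopic location, often at much larger size and with a capsule).
The package turns a semantic segmentation model into an object detector:
segment, assemble a whole-slide confidence map, extract and filter
objects, and score detection quality at the object level.

## 2. The dual-branch model

A single 0.5 μm/px patch large enough to show an entire TLS in context
would be prohibitively large; a small patch at high resolution shows
cytology but no architecture. The model therefore reads two concentric
284×284×3 patches: the *target* at 0.5 μm/px and the *context* at
2.0 μm/px (a 4× wider field of view). Each patch passes through a U-Net
style encoder–decoder with unpadded 3×3 convolutions (two per level, batch
normalization + ReLU after each), 2×2 max pooling, and 2×2 stride-2
transposed-convolution upsampling, with center-cropped skip connections.

**Hooking.** After two up-convolution stages, the context decoder's
feature map has a stride of 4 context pixels = 16 target pixels — exactly
the stride of the target branch's bottleneck. Cropping the central 10×10
window of that context feature map and concatenating it onto the 10×10
target bottleneck aligns the two fields of view pixel-for-pixel. The
context decoder is built only down to this hook level: it carries no
supervised head (the only loss sits on the target branch), so deeper
context-decoder levels would receive no gradient and are omitted.

**Valid-convolution arithmetic.** Each 3×3 valid convolution shrinks the
map by 2 px, so with depth 4 a 284 px input yields encoder sizes
280 → 136 → 64 → 28, a 10×10 bottleneck, and a 100×100 output window
(284 − 184). Input sizes must keep every pooled size even and every skip
crop centered; `model_config()` rejects invalid sizes and lists feasible
ones. Because the network is fully convolutional, weights trained at one
input size run at any other feasible size (`resize_model_input()`); the
scaled-down study below trains at 220 px and infers at 284 px.

**Filter schedules.** Three architecture facts are fixed by design:
the hooked bottleneck must be 10×10×**440**, the output must sit on the
0.5 μm/px grid, and the trainable parameter count must be approximately
**25 million**. The default schedules — target branch [14, 28, 56, 112]
with a 224-channel bottleneck; context branch [54, 108, 216, 432] with a
960-channel bottleneck and the hook taken at the 216-channel decoder level
(224 + 216 = 440) — satisfy all three simultaneously (25,292,939
parameters; `count_parameters()` counts every trainable scalar including
batch-norm scale/shift). A schedule pair cannot be chosen freely: making
the branches uniformly narrower or wider breaks either the 440-channel or
the 25 M constraint, and plain doubling schedules cannot hit both at once,
which is why the context branch is deliberately wider than the target
branch. The layer-level primitives (im2col + GEMM convolution, pooling,
transposed convolution, batch norm) are implemented in C++ within this
package, with the backward pass verified against central finite
differences to ~1e-8 relative error in the test suite.

## 3. Training

* **Labels.** Annotations rasterize with precedence
  ignore (lymph node) > GC > TLS > Rest > unlabeled; GC pixels override
  the surrounding TLS (nested labeling), and annotated lymph nodes are
  excluded from every loss and metric because they are morphologically
  TLS-identical. Unlabeled pixels are *not* a background class: Rest is
  annotated sparsely, so absence of a label is not evidence of absence.
  The loss is cross-entropy over TLS/GC/Rest masked to labeled pixels
  only; the masking is exact (the gradient at excluded pixels is zero by
  construction and by test).
* **Sampling.** Patch centers are drawn class-balanced: a category is
  chosen with probability ∝ 1/(its annotated pixel count), then a uniform
  annotated pixel of that category. This gives rare categories (GC)
  adequate exposure.
* **Optimization.** Adam at learning rate 1e-4 (default; the scaled-down
  study uses 2e-3 for its tiny model), batch of 6 concentric pairs,
  He-normal initialization from a single seed, L2 weight decay 1e-5 on
  convolution weights. These optimizer constants are package choices
  exposed in `train_config()`/`model_config()`, not claims about any
  reference training run.
* **Augmentation.** Flips, 90° rotations (applied identically to both
  patches and the mask) and mild brightness/per-channel jitter (±10%/±5%).
* **Hard-negative mining.** With exhaustive TLS/GC annotation, every
  detection on a training slide that validates no ground truth is a
  genuine false positive; `mining_iteration()` adds such polygons as Rest
  annotations (tagged with their iteration for auditability), re-trains
  from *fresh* random initialization, and re-evaluates. Original
  annotations are never modified; the bookkeeping (Rest pixel growth
  equals the harvested area not already claimed by an annotation) is
  asserted in the acceptance suite.

## 4. From confidence maps to objects

Tile outputs are assembled at stride = output size, so the output windows
partition the slide: assembly is exact (a coverage counter asserts each
pixel is written once) and trivially seam-free; an overlap-averaging
variant was deliberately not made the default because it would destroy the
bit-exactness that the tests rely on. Probabilities are quantized to
integers 0–255 by `round(p·255)` (quantization error ≤ 0.5/255); pixels
outside the tissue mask are zeroed.

**Scores.** The softmax categories are mutually exclusive, so a confident
GC would punch a hole into its parent TLS's probability. The TLS detection
score is therefore P(TLS) + P(GC) clipped to 255, restoring the biological
nesting; the GC score is P(GC) alone. The alternative (TLS channel only)
is available behind a flag for comparison.

**Thresholds.** Candidate objects are 8-connected regions with score ≥ t
kept at pixel area ≥ s²; `(t, s)` is selected by evaluating the pooled
validation F1 over the full 256×256 grid, with ties broken toward the
largest t, then the largest s (the most conservative equally-good
operating point). The implementation computes connected components once
per t and sweeps s by area cutoffs — exactly equivalent to brute force,
and verified against an independent igraph-based exhaustive oracle in the
tests. The size grid "up to 255²" output-grid pixels corresponds to at
most ≈0.016 mm² at 0.5 μm/px.

**Monotonicity.** For fixed t, raising s only removes objects — a theorem.
For fixed s, raising t cannot grow any region (regions at a higher
threshold nest inside regions at a lower one — also a theorem, and
property-tested on arbitrary random rasters), but it *can split* one
region into several, so object-count monotonicity in t is guaranteed only
when structures are isolated unimodal peaks — the regime real confidence
maps live in. The monotonicity tests therefore draw random mixtures of
isolated unimodal blobs and the nesting tests use unrestricted noise.

**GC filter.** A GC detection is kept iff ≥50% of *its* area intersects
the union of TLS detections ("at least 50%" keeps the exactly-half case).
The direction of the rule is genuinely ambiguous in words; 50%-of-GC is
the default because GCs are much smaller than their parent TLS (the
inverted reading would reject nearly everything), and the inverted rule is
available behind a flag.

## 5. Object-level evaluation

A ground-truth object is a true positive iff a *single* prediction covers
≥50% of its area (union coverage is a flag, not the default — the rule
speaks of "a prediction"); uncovered ground truths are false negatives;
predictions validating no ground truth are false positives. One prediction
may validate several ground truths. Per-slide F1 uses the convention that
a slide with no ground truth scores 1 with no predictions and 0 with any
spurious prediction (the pooled "overall" F1 uses raw pooled counts and
ignores the convention; the two deliberately differ and a test pins the
difference). Overlap fractions are computed exactly on the 0.5 μm/px pixel
grid by pixel counting — detection objects *are* pixel regions, so no
approximation is involved; ground-truth polygons rasterize by the
pixel-center even-odd rule (a 10×10 px axis-aligned square contains
exactly 100 pixel centers). An independent `mgcv::in.out`-based
rasterization oracle cross-checks both the rasterizer and the matcher.

Quantification reports per-category counts, densities per cm² of tissue
(tissue = pixels below a grayscale threshold, default 235, applied at
4 μm/px and held constant across a cohort — enforced at the API level),
and mean object areas in mm². Patient-level grouping takes the maximum
density across a patient's slides and splits each cohort at its median
(strictly above = TLS-high, so an all-tied cohort is entirely TLS-low).

## 6. Encoding features

Each TLS/GC region is encoded by max-pooling the 10×10×440 hooked
bottleneck of a patch pair centered on the region's area-weighted
centroid, giving 440 features. Zero-variance columns are dropped (an
empirical property of a dataset, not an architectural constant), a
k-nearest-neighbor graph (default k = 50) is weighted by the Jaccard
overlap of neighbor sets, and Louvain modularity optimization partitions
it; per-cluster TLS/GC enrichment uses the Yates-corrected chi-square on
the 2×2 in/out × TLS/GC table. Two caveats are documented deliberately:
(i) modularity optimization on *sparse* neighborhood graphs can subdivide
a homogeneous group into several communities (its known resolution
behavior) — cluster counts are implementation-sensitive, and the tests pin
only regime-appropriate facts (exact recovery of well-separated groups in
the dense regime; never mixing disconnected groups in any regime);
(ii) the 2-D embedding emitted for plotting is a principal-component
projection, a deliberately simple side artifact.

## 7. The synthetic study conditions

The generator renders what the detector needs to distinguish, at a
deliberately miniaturized scale chosen once for testability:

* 512×512 px (tests) or 1024×1024 px (default) fields at 0.5 μm/px;
* TLSs as perturbed ellipses (8–16 control points, ≤20% radial jitter)
  with semi-axes 40–70 px, filled with 3 px nucleus discs to 55% area
  (background 5%); half of them carry a centered GC core at 10–35% of the
  TLS area with halved nucleus density and 1.6× nucleus radius on a paler
  base;
* diffuse infiltrates (Rest) at intermediate density without a sharp
  contour; lymph-node confounders at ≈10× the median TLS area with a
  darker capsule rim, labeled LymphNode;
* a fixed H&E-like palette (background ≈ [245,242,245], stroma
  ≈ [230,180,200], nuclei ≈ [80,50,120]) with additive Gaussian pixel
  noise (σ = 3), and a two-level pyramid whose 2.0 μm/px level is the
  exact 4× block average of the 0.5 μm/px level.

What it does **not** emulate: realistic stain variation and deconvolution,
scanner artifacts, pen marks or air bubbles, tissue folds, biological TLS
size/density distributions (real TLSs are hundreds of μm across; the
miniature scale keeps tests fast), or the hard KIRC-style confounder of
CD20-negative T-cell aggregates. Passing tests therefore demonstrate the
*mechanics* of the pipeline — geometry, bookkeeping, optimization,
learnability of contour + density cues — not clinical performance.

**Scaled-down recovery study.** Three seeded repeats, each: 2 training,
2 validation, 2 held-out test slides (4 TLSs each); a reduced-width model
(target [2,4,8,16]/32, context [3,6,12,24]/48 — ≈0.4% of the full
parameter count, hooked bottleneck 44 channels) trained 120 Adam steps at
batch 4 and learning rate 2e-3 on 220 px patches; thresholds optimized on
the validation slides; pooled TLS F1 measured on the test slides, with a
majority of repeats required to reach 0.8. The problem sizes were chosen
as the smallest at which the study is still meaningful; typical repeats
reach F1 = 1.0 on this substrate since color + density make the synthetic
task easy — which is precisely what makes it a mechanics check rather
than a performance claim.

## 8. Numerical choices and degenerate inputs

* Coordinates are 0-based, x-right/y-down, in 0.5 μm/px pixels; pixel
  (r, c) has center (c+0.5, r+0.5). Stored once at full resolution,
  rescaled per level.
* Argmax rasters break ties by the fixed order TLS < GC < Rest; pixels
  with zero evidence in every category get argmax 0.
* Region outlines are traced along pixel edges (left-turn preference, so
  8-connected regions give one outline); for hole-free regions the traced
  polygon's shoelace area equals the pixel count exactly. Holes are
  discarded by design — detections are solid anatomical objects.
* Zero-area polygons are skipped with a warning at rasterization; a batch
  whose slide has only lymph-node annotations is a configuration error
  (no loss-eligible pixels); divergent (non-finite) training loss aborts
  with a diagnostic; thresholds outside 0..255 and inverted
  inside/outside fixture probabilities are configuration errors.
* Reflect padding supplies context beyond slide borders, so a slide
  smaller than one input tile is handled by padding, never an error.

## 9. Known limitations

Training at full 284 px geometry on a single CPU is slow (≈1.5 s per
batch-4 step for the reduced model; the full 25 M-parameter model is
practical for inference but not for CPU training); no GPU path exists.
The GeoJSON reader supports the QuPath classification dialect only.
Overlapping *predictions* in annotation form lose pixels to each other
when painted into a single label raster (detections cannot overlap by
construction, so this affects only cross-annotator comparisons). The
tissue threshold approximates fat exclusion purely by intensity; no
fat-specific detector is attempted.
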