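---
title: "Ranking intraoperative bleeding from surgical video: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking intraoperative bleeding from surgical video: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bleedrank)
```

## The problem

Transurethral resection of the prostate (TURP) is performed through a
cystoscope; intraoperative bleeding clouds the irrigated surgical field and
is its most common complication. Experienced urologists grade the visual
clarity of a clip on a four-level ordinal scale — 0 *excellent*, 1
*acceptable*, 2 *slightly bad*, 3 *bad* — but doing this by eye across many
three-minute clips is slow and subjective. `bleedrank` automates the
grading: it quantifies how much of each frame is blood-red, summarises a
clip by two numbers, and classifies that 2-d point into a bleeding level.

Two domain obstacles shape the design:

1. **The cutting loop glows red.** The electrosurgical electrode produces a
   bright red-orange glare that a colour rule cannot distinguish from blood.
   A segmentation network finds the loop so its pixels can be removed before
   any blood is counted.
2. **Clips are scored by three raters.** The consensus rule is majority
   vote: unanimous or 2-of-3 agreement fixes the label; full disagreement
   flags the clip for re-evaluation (`consensus_label()` returns `NA`).

## Pipeline

For each video: sample frames at a uniform stride (deterministic
`floor(i * L / n)` indices rather than random draws, so a clip always yields
the same frames), predict a cutting-loop mask per frame, convert to YCbCr
and threshold the chroma channels to get the red mask, clear the loop pixels,
then compute per-frame **bleeding ratio** (blood pixels over non-loop
pixels) and **region count** (connected components surviving a minimum-area
filter). A video's feature point is the arithmetic mean of the per-frame
values; means were chosen over sums so the feature does not scale with clip
length. The four classifiers — KNN, Gaussian naive Bayes, random forest,
soft-margin SVM — consume min-max-normalized features, with the bounds
fitted on the training set only and stored in the fitted object.

### Colour model

YCbCr uses the BT.601 full-range transform, the common default of imaging
libraries. A pixel is blood-red when `Cr >= 150` and `Cb <= 130` (8-bit
scale). These defaults let saturated red pass easily (pure red has Cr = 255,
Cb ≈ 85) while neutral gray (Cr = Cb = 128) and white glare fail; both are
configurable (`red_thresholds()`) since lighting varies across endoscopes.
The denominator of the bleeding ratio is the *non-loop* pixel count: loop
pixels are eliminated, so they are neither blood nor visible field, and a
large loop should not dilute the ratio.

Region counting defaults to 8-connectivity with a 20-pixel minimum area
specified at 256×256 and scaled with frame area, suppressing speckle without
deleting genuine small bleeds. Counting is exact flood-fill labelling
(compiled), checked in the tests against an independent breadth-first-search
oracle.

### The residual U-Net

The loop segmenter is a compact fully-convolutional encoder–bridge–decoder
with residual blocks in place of pooling: each encoder stage halves the
resolution with a stride-2 convolution inside a residual block (projection
shortcut), the bridge is a residual block at the bottleneck
(`base_filters * 2^depth` channels), and each decoder stage upsamples ×2
(nearest-neighbour), concatenates the matching encoder activation and
applies another residual block; a final 1×1 convolution yields per-pixel
logits. No deep-learning framework is used: the forward and backward passes
are written in R over compiled im2col/col2im kernels, and the backward pass
is verified against finite differences in the test suite. This keeps the
model fully deterministic for a fixed seed and byte-reproducible across
serialisation.

Design choices worth recording:

* **Post-activation residual blocks without batch norm.** At the scales this
  package trains (base 8 filters, 64×64 inputs) batch norm added complexity
  and batch-size sensitivity without measurable benefit; He initialisation
  plus Adam is sufficient for the colour-plus-brightness cue that separates
  the loop from blood.
* **Loss `bce+dice`** (sum). Cross-entropy is well-conditioned early in
  training; the Dice term directly optimises overlap for small foreground
  objects. Either alone also works on the synthetic task.
* **Strict `>` at the mask threshold** (default 0.5), so an untrained
  zero-logit model yields an *empty* mask rather than a full one.
* **Empty ∩ empty convention:** `iou` and `dice` return 1 when both masks
  are empty — perfect agreement, and it keeps averages over loop-free frames
  meaningful.
* **Resizing:** frames are resized to the model input bilinearly; predicted
  masks are thresholded at model resolution and returned to the frame's
  resolution by nearest-neighbour, which preserves binarity.

Default problem sizes for the training experiments are 64 training and 16
held-out frames at 64×64 with base 8 filters and 20 epochs, and a 200-step
single-image overfit check; these reproduce the behaviour of interest
(held-out IoU well above 0.5, overfit IoU near 1) at desktop cost.

### Classifiers

Hyperparameters are deliberately plain — `k = 5` neighbours, RBF SVM with
`C = 1`, 100 trees, Gaussian class-conditionals — and all exposed through
`classifier_spec()`. KNN is implemented in the package because its
tie-break is pinned down: majority vote among the `k` nearest by Euclidean
distance, ties broken by the smaller mean distance among tied labels, then
by the lower score (the clinically conservative choice); the tests compare
it against an exhaustive scan. The other three are fitted with the standard
R implementations (`e1071`, `randomForest`); the SVM handles four classes
one-vs-one, as libsvm does natively. Labels are treated as nominal
throughout — ordinality enters only in evaluation.

### Evaluation

The confusion matrix has actual levels in rows and predictions in columns.
The *revised* view formalises "adjacent levels are clinically acceptable":
every off-diagonal count at distance exactly 1 moves onto the diagonal of
its own row; cross-level errors (distance ≥ 2) stay. This transfer preserves
the grand total, never lowers the trace, and is idempotent — all three are
property-tested on random matrices. Plain and revised accuracy/precision/
recall come from the corresponding matrix; precision and recall are
macro-averaged over classes (classes with a zero denominator are excluded),
with micro-averaging available behind a flag (in one-vs-rest multi-class it
collapses to accuracy). Rank agreement is plain Pearson correlation over
the integer scores; it errors on constant vectors, where it is undefined.

## The synthetic data generator

The clinical clips behind this kind of system are private, so the package
ships a generator that emulates the features the pipeline actually keys on,
and is itself first-class, tested code:

* pinkish tissue background with smooth illumination drift and pixel noise,
  whose chroma sits safely *below* the red thresholds;
* dark-red elliptical blood blobs; expected count (1, 4, 9, 16) and total
  area fraction (0.005, 0.03, 0.10, 0.25) grow strictly with the level.
  The per-frame blob count is Poisson; blob colours land well above the Cr
  threshold so the generator's blood is, by construction, what the colour
  rule detects;
* optionally, a bright red-orange arc with a Gaussian glow standing in for
  the cutting loop. Its radius, span, thickness and glow width vary widely
  from frame to frame, *independently of the bleeding level* — exactly the
  confound that loop elimination removes. Ground truth is defined as the
  painted arc including its visible glow (hardware + halo). Blood hidden
  behind the loop is excluded from the blood mask.

Per-frame seeds are derived deterministically from the video's master seed,
so datasets reproduce exactly. A level's blob areas are drawn around the
target fraction; Monte-Carlo tests confirm the realised mean blood fraction
stays within ±30% of the target (union overlap and edge clipping eat some
area).

What the generator does **not** emulate: irrigation fluid dynamics, motion
blur, specular highlights, instruments other than the loop, camera
vignetting, and the long-tailed severity distribution of real surgery.
Passing the synthetic benchmarks therefore demonstrates that the pipeline's
machinery is correct and that loop elimination removes the confound it is
designed to remove — not that the specific thresholds or classifiers
transfer to clinical video unchanged. On real data the colour thresholds
and the minimum region area are the first knobs to recalibrate.

## Experiments the package reproduces

`scripts/acceptance.R` reruns, from scratch and seeded: (i) the full
pipeline on a 40-video synthetic dataset (10 per level, 20 frames, 128×128)
with a 50/50 stratified split, reporting plain and revised held-out accuracy
for all four classifiers; (ii) the with/without-loop-elimination comparison
over five dataset seeds, reporting both mean Pearson correlations — the
directional claim is that elimination never hurts and typically helps;
(iii) segmenter training at the sizes above, reporting held-out IoU/Dice
and the single-image overfit IoU. These sizes were chosen as the smallest
that exercise every stage convincingly on one CPU.

## Known limitations

* The segmenter is trained and evaluated on synthetic loops; no claim is
  made about clinical IoU.
* The bleeding ratio treats every red pixel equally; pooled blood and fresh
  arterial bleeding are not distinguished.
* Ordinality is ignored at fit time; with larger datasets an ordinal model
  (e.g. proportional odds) would use the label structure directly.
* Frame I/O is PNG-only.
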