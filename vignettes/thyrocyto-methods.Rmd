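---
title: "Models and methods behind thyrocyto"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind thyrocyto}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

thyrocyto is a desk-scale re-implementation of a multi-stage diagnostic
pipeline for thyroid fine-needle-aspiration (FNA) cytology. A digitised
liquid-based smear enters as a set of RGB tiles; out comes a Bethesda
(TBSRTC) category — I (nondiagnostic), II (benign), V (suspicious for
malignancy) or VI (malignant) — optionally refined by a predicted
BRAF-V600E status. This vignette explains each model, its assumptions and
parameters, how the synthetic data generator that drives all training and
testing works, and what the package's passing tests do and do not show
about clinical data.

## The synthetic cytology generator

No public FNA image corpus accompanies this problem, and the package must
be trainable and testable offline, so the generator is a first-class
module rather than a fixture. It emulates Papanicolaou / H&E-stained
liquid-based smears at a schematic level:

* **Nuclei** are textured ellipses in 17 classes `C1..C17`. `C1-C3` are
  papillary-carcinoma (PTC) phenotypes: larger, paler, irregular
  boundaries. `C4` carries a nuclear groove (a dark linear membrane fold
  across the nucleus) and `C5` an intranuclear pseudo-inclusion (a bright
  cytoplasm-coloured disk) — the two PTC hallmarks. `C6-C8` are benign
  thyroid follicular epithelial cells (TFEC): smaller, darker, rounder.
  `C9-C17` are schematic stand-ins for the long tail (macrophages,
  lymphocytes, colloid, debris, ...); their exact styling is a fixture
  convention, chosen for visual distinctness and rough biological
  plausibility (e.g. lymphocytes: 3 px radius, dense dark chromatin at
  the default 256-px/20x-equivalent scale).
* **Clusters**: a configurable fraction of objects is rendered as 2-12
  overlapping member ellipses sharing one instance label, with member
  counts stored so the adequacy rule's group semantics can be
  ground-truthed.
* **Debris**: red blood cells (small saturated-red disks) and colloid
  smears are painted but *never* labelled — they are the true-negative
  population for the HSV debris filter.
* **Appearance shifts**: `perturb_appearance()` applies per-channel gamma
  then affine gain/offset, emulating stain and scanner variation.

Every patch carries its instance mask and class table; rendering is a pure
function of `(config, seed)` down to the byte (all randomness flows
through one seeded RNG restored afterwards; images are quantised to the
8-bit grid so PNG round-trips are lossless).

**Slide labels.** A slide (a list of tiles) gets its ground-truth TBS
label from a documented fixture rule: it is TBS I when the adequacy
left-hand side `10*(N_PTCA + N_TFECA) + 5*(N_PTCB + N_TFECB)` computed on
the generated objects falls below 60; otherwise, with `f` the atypical
fraction (objects in C1-C5 over all epithelial objects), the slide is VI
when `f > 0.5`, V when `0.1 < f <= 0.5`, II otherwise. The V/VI band
bounds (0.1, 0.5] are fixture conventions chosen so all four labels occur;
they are config-exposed (`tbs_v_band`). BRAF-V600E status is drawn from a
logistic link `plogis(-4 + 8 f)`, which makes the gene classifier
learnable while keeping mutation prevalence low on benign slides —
roughly 3% at `f = 0.05` and 92% at `f = 0.8`.

**Cohorts.** `render_cohort()` draws per-slide class mixes from four
archetypes (nondiagnostic / benign / suspicious / malignant, default
probabilities 0.15/0.35/0.25/0.25) with 12-18 objects per tile for
adequate archetypes. The within-group shares favour the group-forming
classes C1/C2/C6/C7 so that adequate archetypes clear the weighted count
of 60; labels still come from realized counts through the fixture rule,
never from the archetype.

**What the generator does not emulate**: chromatin texture statistics of
real nuclei, three-dimensional focal planes, overlapping transparency,
smear artifacts, or the actual colour distributions of named stains and
scanners. Tests passing on this fixture demonstrate that the pipeline's
machinery is correct and learnable end to end; they do not certify
clinical performance.

## Nuclear segmentation

The segmentation model is a compact U-shaped encoder-decoder.
Stage *i* uses `base_width * 2^(i-1)` channels (two 3x3 conv+ReLU per
stage), with max-pooling between encoder stages and nearest-neighbour
upsampling plus skip concatenation in the decoder. With `pyramid_fusion`
on, the decoder's output at *every* scale is upsampled to full resolution,
concatenated, and fused by a 1x1 projection before the sigmoid foreground
head, so coarse context and fine boundaries meet directly at the output.
The design goal is parameter economy: the tiny preset (depth 3, base
width 8, 128-px input) has about 30k parameters, under 10% of a
VGG16-backbone DeepLab-v1-style reference scaled to the same first-stage
width (`deeplab_reference_params()`), comfortably within the stated 20%
budget.

Training minimises pixel-wise binary cross-entropy plus Dice loss with
equal weights (Dice keeps gradients alive when foreground is sparse) under
Adam at `lr = 1e-3`. The networks are implemented from scratch on
im2col+BLAS and depthwise convolution kernels (`src/convops.cpp`) with
hand-derived backpropagation; every layer's gradient is verified against
central finite differences in the test suite. On the synthetic benchmark
(50 patches, 30 epochs, one CPU) the tiny preset reaches held-out Dice
around 0.94 in about five minutes.

## Debris rejection and detection post-processing

Nucleus-like debris — above all red blood cells — is removed in HSV space:
connected components whose *median* hue/saturation/value falls inside a
reject range are dropped whole. Filtering is component-wise, never
pixel-wise, because pixel-wise thresholds fragment nuclei. Range bounds
are `[low, high)` (upper bound exclusive); the default reject ranges,
hue in [0.95, 1] or [0, 0.05] with saturation at least 0.5, target red
debris and are stain-dependent, hence config-exposed.

The filtered mask becomes detections: connected components larger than
`max_single_area` (2500 px^2 at 256-px tiles, scaled by `(tile/256)^2`)
are split by a distance-transform watershed seeded at distance-map maxima
at least `min_peak_distance` (7 px) apart; an object is a *cluster* when
its area exceeds `cluster_area_threshold` (1200 px^2) or it contains two
or more seed peaks, else a *nucleus*; objects under `min_area` (30 px^2)
are discarded but counted, so the audit identity `detections in = calls
out + rejected + discarded` always balances. Each detection's score is the
mean foreground probability over its pixels — the `SC` statistic that
slide aggregation later summarises. All these defaults were calibrated
once on the synthetic fixture and are config-exposed.

## Nuclear morphometry and the morphology classifier

Nineteen features per nucleus, in fixed order: area, perimeter, equivalent
diameter, major/minor axis, aspect ratio, eccentricity, circularity
(4 pi A / P^2), solidity, extent, orientation, then luminance mean/sd/min/
max, hue/saturation/value means, and gradient energy. Geometry uses pixel
counts and second-order central moments (with the 1/12 pixel-square
correction); the perimeter is the boundary-polygon length; circularity is
clipped at 1.05 because digital perimeters understate very small objects;
solidity uses a convex hull over pixel corners so it cannot exceed 1;
orientation lies in (-pi/2, pi/2]. A gradient-boosted (XGBoost) classifier
over these 19 features — trained on the 9-role reduction PTCA/PTCB/PTCC/
TFECA/TFECB/TFECC/NUCLEAR/INCIS/OTHER — provides the second, independent
opinion used by the agreement gate. It is configured with `lambda = 0` and
`min_child_weight = 0`, making the fit a pure function of the empirical
distribution (exactly invariant to duplicating the dataset).

## The cell classifier and the agreement gate

The neural cell classifier is a small large-kernel-attention network: each
stage block projects its input (1x1 conv + ReLU), computes an attention
map through a depthwise 5x5, a depthwise dilated 7x7 (dilation 3, giving a
19-px receptive field), and a pointwise convolution, multiplies the
projection by this map, projects back and adds the residual. The head
concatenates channel means with channel maxima before the 17-way linear
layer — maxima preserve small salient structures such as a bright
pseudo-inclusion that spatial averaging would wash out. Training follows
the published recipe: AdamW with weight decay 0.05 and cosine-annealed
learning rate from 0.001, with flip/rotation/colour-jitter augmentation
and random cropping; the desk-scale preset uses 64-px crops (224 remains
the full-scale default) and minibatch 4, because the tiny net needs a few
thousand optimizer updates to leave its initial plateau.

For the six epithelial classes (C1-C3, C6-C8) a cell only *enters the next
step* when the neural and the morphology classifiers agree; disagreeing
cells are REJECTED and excluded from slide aggregation. Agreement is
evaluated at role level by default (the morphology model is trained on
roles), with an exact-id flag available. The gate never relabels — its
output is the network's class or REJECTED.

Two training-protocol choices matter a great deal in practice and are
worth stating plainly. First, inside the slide pipeline both classifiers
are trained on the *detector's own outputs* over the training cohort —
windows, instance masks and morphometry come from detections labelled by
ground-truth overlap, never from the pristine ground-truth masks. Pale
papillary-carcinoma nuclei segment slightly eroded, and a morphology model
fit on clean masks mis-sizes exactly those cells at inference; matching
the train and inference distributions removes that failure mode. Second,
the pipeline's classifier receives the queried instance's mask as a
fourth input channel: classification windows on a crowded tile contain
several cells, and without a pointer to the queried object the network
cannot know which one it is rating (nor how far a cell group extends,
which separates the large-group from small-group classes).

## Slide features and diagnosis

Accepted calls aggregate into a 104-attribute slide vector whose registry
is versioned and swappable: per-role counts `N-*`; mean/median
classification probabilities `AVG-P-*`/`MEDI-P-*`; mean/median detection
scores `AVG-SC-*`/`MEDI-SC-*`; global mean/median of each of the 19
morphometry features over accepted *nucleus-kind* objects
(`AVG-*-NUCLEAR`/`MEDI-*-NUCLEAR`; clusters contribute to counts and
scores but not to nuclear morphology); per-role areas; and three totals
including the adequacy left-hand side. Empty roles use a 0 sentinel rather
than missing values so the tree models need no missing handling.

Diagnosis is two-stage. First the adequacy rule: a slide is TBS I
(nondiagnostic) when `10*(N-PTCA + N-TFECA) + 5*(N-PTCB + N-TFECB) < 60`,
a weighted group count with weights equal to the average cells per
large/small epithelial group and the conventional sixty-follicular-cells
minimum; the inequality is strict, and raising any count can only keep or
lose TBS I status (monotonicity is property-tested). The grouping of the
formula follows the parameter definitions (each weight multiplies the sum
of its two group counts); written with explicit parentheses it is the
six-groups-of-ten adequacy convention. Only when the rule passes is the
gradient-boosted slide classifier consulted: a 3-class model (II/V/VI) and
a 2-class model (II vs V+VI, merged before training) are both supported,
tuned by grid search (tree depth {3,5,7}, learning rate {0.05,0.1,0.3},
rounds {100,300}, subsample {0.8,1.0} — the package's default grid) under
stratified 5-fold cross-validation, best configuration refit on all data.
III and IV are never output labels.

The cascade: when the slide classifier outputs TBS V, a binary
gradient-boosted BRAF-V600E model over the same 104 features is consulted
and the final label becomes II (gene 0) or VI (gene 1); every other
prediction, and V without a gene model, passes through unchanged. Because
the cascade *always* resolves a V call to II or VI, applying it blindly
would destroy every correctly suspicious (true-V) slide; the package
therefore evaluates it the way it is deployed clinically — on II/VI-truth
slides the image model misread as V, where it converts guaranteed errors
into partial correct assignments — and reports cohort accuracy on the
image-only two-stage prediction, which still emits V.

Evaluation metrics come from confusion counts with Wald normal
approximation intervals `p ± 1.959964 sqrt(p(1-p)/n)` clipped to [0, 1].
The Wald choice is verified in the tests by reproducing all three
published sensitivity intervals of the indeterminate-lesion panel to four
decimal places.

## Image appearance migration

Cross-scanner and cross-stain colour shifts are corrected by matching
foreground colour statistics to a reference domain. Because cytology is
dispersed cells on glass, global histogram methods built for solid tissue
misbehave; the map is therefore (1) restricted to a cell-foreground mask,
(2) estimated once per slide (one source profile from all tiles pooled —
per-tile profiles would flicker), and (3) affine per channel,
`x -> (x - mu_src) * sigma_ref / sigma_src + mu_ref` (unit gain when
`sigma_src = 0`), in Reinhard's log-LMS opponent space (one luminance +
two chroma channels; fixed conversion matrices, LMS floored at 1e-4
before the log so black pixels stay finite). Percentiles are stored in
profiles but unused by the default map. Background blends through a
feathered mask — weight 1 inside the mask, Gaussian falloff (default
3 px) outside — so no halo forms while foreground statistics match
exactly up to clipping and 8-bit rounding.

The foreground mask itself must survive the very shifts it corrects, so
both its criteria adapt to the tile: glass luminance is estimated as the
95th luminance percentile, and the saturation cut is at least twice the
median saturation (glass dominates the median). An H&E preset tightens
the saturation criterion, since eosin pinks the background.

## Numerical and design choices

* Coordinates are 0-based with half-open boxes, row-major rasters, origin
  top-left; GeoJSON polygons wind counter-clockwise.
* Argmax ties break to the lowest class index everywhere.
* All training is deterministic given seeds: single-threaded xgboost, R
  RNG isolated via an internal `with_seed()`, weight init in fixed layer
  order. Two runs with the same data and seed give identical losses,
  hyper-parameter choices and predictions.
* Instance masks are written as 16-bit TIFF (the PNG writer available
  here does not expose 16-bit output); images as 8-bit PNG; everything
  else is JSON/CSV.
* Problem sizes in the tests and the acceptance script are desk-scale
  choices: segmentation trains on 50 patches of 128 px for 30 epochs; the
  cell benchmark uses 600 crops over 6 visually distinct classes for 40
  epochs; the end-to-end experiment uses cohorts of a few hundred
  synthetic slides of 2-3 tiles. These sizes make each stage trainable on
  one CPU in minutes while leaving the statistical questions (recovery of
  fixture labels, direction of the cascade benefit) answerable.

## Known limitations

The generator's simplicity means classifier accuracies here say nothing
quantitative about clinical WSIs; the published cohort-level numbers
(e.g. 93% TBS-I accuracy, 95%+ 17-class accuracy) require the original
multi-centre data and are out of scope. The watershed splitter
under-segments heavily overlapping clusters by design (they are meant to
be detected as clusters). The appearance migration is affine per channel;
strong non-linear stain distortions (H&E to Pap) are only partially
corrected. The 17-class schema's C9-C17 styles are schematic stand-ins,
and the class-to-role map is config-exposed in case a different ordering
of the published class table is needed.
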