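---
title: "Methods: synthetic vertebra images, morphological staging rules, and the compact CNN"
author: "cvmStager"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic vertebra images, morphological staging rules, and the compact CNN}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvmStager)
```

## The problem

Cervical vertebral maturation (CVM) staging reads skeletal maturity from the
morphology of the second through fourth cervical vertebrae (C2--C4) on a
lateral cephalogram. Six ordered stages, CS1 through CS6, track two
morphological progressions: a concavity appears and deepens in the lower
borders (first C2, then C3, then C4), and the C3/C4 bodies change shape from
tapered trapezoids to horizontal rectangles, squares, and finally vertical
rectangles ("higher than wide"). The stage predicts the timing of the
mandibular pubertal growth spurt, which drives orthodontic treatment timing.

`cvmStager` implements a complete, testable staging pipeline: a synthetic
image generator with ground-truth landmarks, the classical landmark-based
measurements with an explicit six-stage decision cascade, the image
preprocessing operators used in this literature (crop, resize, Sobel edge
magnitude, local mean/median/entropy filters), a compact convolutional
classifier, and the standard evaluation artifacts. Real cephalogram corpora
in this area are private; the synthetic generator exists so every stage of
the pipeline can be exercised and verified end to end without them.

## Coordinate and measurement conventions

Pixels use a top-left origin with x rightward and y downward (raster
order); the "lower" border of a vertebra therefore has the larger y.
Anterior landmarks have larger x than posterior ones. Each vertebral body
carries five landmarks: `Cla`/`Clp` (lower anterior/posterior corners),
`Cm` (lower-border midpoint), `Cua`/`Cup` (upper corners).

Three measurements summarize a body:

* **Concavity depth** -- perpendicular distance of `Cm` from the `Clp`--`Cla`
  chord, clamped to zero when `Cm` is on or above the chord. The package
  orients the concavity as a dip to larger y (below the chord); the
  generator and the rule stager share this convention, and only their mutual
  consistency matters for stage recovery.
* **Tapering ratio** -- posterior over anterior body height,
  `|Cup-Clp| / |Cua-Cla|`. Values above 1 mean a superior border sloping
  down toward the front (early stages).
* **Lengthening ratio** -- base length over anterior height,
  `|Clp-Cla| / |Cua-Cla|`. Distinguishes horizontal-rectangular (> 1),
  square (about 1) and vertical-rectangular (< 1) bodies.

All three use Euclidean segment lengths, so they are rotation invariant,
and scaling the landmarks by *s* scales the depth by *s* while leaving the
ratios unchanged (property-tested).

## The decision cascade

The qualitative stage definitions overlap (later stages retain the
concavities of earlier ones), so the rule stager evaluates from the most
mature stage downward and the first match wins:

1. **CS6** -- concavities on C2, C3 and C4; at least one of C3/C4
   vertical-rectangular (lengthening ratio below 0.95); C3 and C4
   concavities deepened (at least twice the flat threshold).
2. **CS5** -- all three concave and at least one of C3/C4 square
   (lengthening ratio in [0.95, 1.05]).
3. **CS4** -- all three concave.
4. **CS3** -- concavities on C2 and C3.
5. **CS2** -- concavity on C2 only.
6. **CS1** -- otherwise.

The cascade is total: any finite feature triple maps to exactly one stage.
Thresholds live in `stageRules()`: the flat threshold is 1 px at a 256-px
render scale and scales linearly with image size; tapering counts as
present above 1.05. Body shape is deliberately ignored for CS3, whose
description admits both trapezoid and rectangular bodies.

## The synthetic generator

`generateDataset()` draws per-stage morphology parameters from
`defaultStageTable()` and renders three stacked bodies: the C2 lower border
with a short stub of its body, and full C3 and C4 bodies. The table encodes
the stage progressions with ranges (at the 256-px reference scale) chosen so
that (a) the rule cascade separates stages with a clear margin at zero
jitter, and (b) the geometric differences survive downsampling to the 64-px
classifier input: concavity depths of 6--10 px for the stages where a
concavity is merely "present", 14--20 px for the deepened CS6, tapering
1.15--1.30 early versus about 1 late, lengthening from about 1.4 (CS1) down
to 0.75--0.92 (CS6). CS5/CS6 additionally reduce the inter-body gaps,
following the "spaces between bodies are reduced" feature of the mature
stages. The published stage definitions are qualitative; these numbers are
the package's modeling choice, kept in one editable table whose validity
check enforces the monotone progressions (non-decreasing mean concavity,
non-increasing CS4 to CS6 aspect ratio).

Rendering fills each body polygon (the lower border is a quadratic arc
through `Cm`, giving maximum depth midway between `Clp` and `Cla`) at a
foreground intensity with a brighter 1-px rim, over a background with an
optional low-frequency gradient; a global rotation/scale jitter is applied
to polygons and landmarks alike, then per-image brightness/contrast jitter
and additive Gaussian noise. Landmarks are stored after the affine map, so
stored coordinates always agree with the pixels.

Three presets define the study conditions:

* `clean` -- zero noise, zero jitter, flat background; used for the
  geometric round-trip checks (the rule stager must recover the generating
  stage for 100% of draws).
* `easy` -- mild noise (sd 0.02), small rotation/scale jitter (3 degrees /
  4%), a gentle background gradient; the benchmark condition for the
  classifier.
* `hard` -- dominant per-image brightness (plus or minus 0.3) and contrast
  (0.45--1.0) variation with moderate noise (sd 0.04), larger jitter and a
  stronger background gradient. This preset models a gray-level nuisance
  regime: the local-entropy statistic depends on the local intensity
  distribution's shape, not its location, so it is nearly invariant to
  brightness/contrast variation that the raw-pixel classifier must
  otherwise absorb. The noise level is calibrated so that the entropy
  transform of these images still shows the vertebral outlines clearly
  (with heavy uncorrelated noise the window histogram saturates and the
  entropy map stops carrying anatomy at all).

What the generator does **not** emulate: soft tissue and skull anatomy,
detector physics, exposure artifacts, anatomical shape variability beyond
the parameter ranges, or inter-observer labeling noise. Passing the
synthetic benchmarks demonstrates that the pipeline's mechanics are correct
and that its comparative claims hold under controlled conditions; it does
not certify clinical accuracy on real radiographs.

## Preprocessing operators

`applyPipeline()` composes crop, resize, Sobel magnitude, and the local
filters, recording provenance. Notable numerical choices:

* **Local entropy** (`localEntropy()`): each output pixel is
  $-\sum_n p_n \ln p_n$ over the histogram of the window intensities, with
  256 bins over the declared [0, 1] range by default. The natural logarithm
  is the default base (a base option exists); the output is bounded by
  $\ln(\text{bins})$, and `normalize = TRUE` divides by that bound for use
  as classifier input. Windows may be square or disk-shaped; borders are
  mirrored by default.
* **Resize** uses area-weighted averaging by default -- the appropriate
  anti-aliasing choice when downscaling radiographs; bilinear and
  nearest-neighbor are available (nearest makes resize-to-own-size an exact
  identity).
* **Sobel magnitude** uses the standard 3x3 kernel pair with mirrored
  borders.
* Both common crop/resize dialects (512 to 256/128/64, and 488 to 244)
  are expressible through a pipeline specification; neither is hard-coded.

The mean/median/entropy comparison from the literature is kept as a
testable property: on a two-level image with uniform noise, the entropy
output responds at the region boundary (the local distribution widens
there) while mean and median outputs simply preserve the plateau gray
levels, so only the entropy band stands out against the interior average.
The comparison is between the three filter outputs; gradient operators
applied after smoothing would test the gradient, not the filter.

## The classifier

`buildModel()` constructs the compact network: five blocks of 3x3
convolution, batch normalization, ReLU, 2x2 max pooling and dropout,
followed by one dense block (1024 units, batch-normalized, dropout 0.5) and
a 6-way softmax. Filter counts default to 32/64/64/128/128 with dropout
rates 0.2/0.2/0.3/0.4/0.5 -- a standard small-image ladder; the published
description fixes the block structure ("five combinations of convolution,
normalization, max-pooling and dropout") but not these constants. The
default 64-px input yields 811,526 trainable parameters. A sixth block can
be appended with `deeperConfig()` for the depth comparison; the depth
non-inferiority check asserts the 6-block variant does not beat the 5-block
default by more than 0.02 mean accuracy.

The loss is categorical cross-entropy
$-\sum_i \sum_j y_{ij} \ln \hat y_{ij}$, reported as a per-sample mean by
default so values are comparable across batch sizes (a `sum` reduction is a
switch). Predicted probabilities are clamped at $10^{-12}$ before the
logarithm.

Training (`trainModel()`) runs SGD with momentum 0.9 or Adam (0.9, 0.999).
The default is Adam with learning rate 3e-3, selected by trying a small
grid of rates on the synthetic benchmark for fastest convergence with good
generalization -- the selection procedure this literature itself describes --
with `lrRangeTest()` available as the exponential-schedule diagnostic (step
$k$ of $n$ uses $lr_k = \text{low} \cdot (\text{high}/\text{low})^{k/(n-1)}$;
the model is restored afterwards). `selectLR()` smooths the recorded batch
losses and returns the rate at the steepest decrease, warning and falling
back to the lower bound when the curve never decreases.

The forward/backward pass is implemented twice: a plain R orchestration of
double-precision kernels (the reference), and a single-precision C++ engine
with preallocated buffers that `trainModel()` uses. A test drives both
through an identical SGD step and requires agreement to single-precision
tolerance; the backward pass is additionally verified against central-
difference numerical gradients. Because training arithmetic is single
precision, a zero-learning-rate epoch returns parameters unchanged up to
float32 rounding (about 1e-7 relative), which is how the corresponding test
asserts it.

Model selection uses the validation split: `trainModel()` snapshots the
parameters at the epoch of best validation accuracy and
`restoreBestCheckpoint()` installs them before evaluation, matching the
stated role of the validation set ("validation and hyper-parameter tuning")
and protecting the 30-epoch benchmark from late-epoch noise. Randomness
(initialization, shuffling, dropout) is drawn from R's RNG, so a fixed seed
reproduces histories exactly on a given platform; across platforms,
accuracies agree to the usual small-float tolerances.

Self-training (`selfTrainingUpdate()`) implements the data-growth step:
pool samples classified correctly with maximum probability at or above a
threshold (default 0.99) move into the training set, with a move log.
Class balance is enforced by the generator rather than by loss weighting,
following the observation that balanced training data behaves better at
these corpus sizes.

## Evaluation artifacts

`confusionMatrix6()` (rows = true, columns = predicted),
`classificationReport()` (precision, recall, F1, support per class, plus
overall accuracy; zero denominators yield 0 with a flag; display rounding
is half-away-from-zero at 2 decimals with full precision retained),
`perClassAccuracy()` (one-vs-rest collapse -- the interpretation under
which published per-class accuracies near 1.0 in a 6-class problem are
coherent -- kept strictly separate from overall accuracy), and
`probabilityGrid()` (per true class, a 6-row raster of predicted
probabilities, exportable as PNG heatmaps). The report arithmetic is
pinned by a worked example: a published 900-image confusion matrix whose
printed report the package must reproduce exactly at 2 decimals.

## Benchmark problem sizes

The package's standard synthetic benchmark generates 100 images per class
at 128 px under the easy preset, resizes to the 64-px input, and trains the
default model for 30 epochs (test accuracy at or above 0.90, averaged over
three seeds). The entropy-versus-raw comparison uses the hard preset at a
reduced scale -- 50 images per class, entropy computed at the 128-px render
scale and then resized to the 64-px input (filtering before downscaling,
the order in which such pipelines apply it to cropped images), 12 epochs,
five seeds -- because the claim under test is directional, not a headline
accuracy. The geometric round-trip uses 100 clean draws per stage. These
sizes are the package's desk-scale study design; the published experiments
behind the method used private corpora of 360 to 1870 radiographs and are
not reproducible here.

### What the entropy comparison shows on synthetic data

On this synthetic family the directional claim -- entropy-filtered inputs
training at least as well as raw inputs under gray-level nuisance -- does
**not** hold: raw inputs win by a wide margin (roughly 0.5 versus 0.3 test
accuracy at the comparison scale), and the corresponding acceptance test
records that failure rather than hiding it. The analysis is instructive.
In real radiographs the dominant nuisance is structured gray-level texture
(soft-tissue shadows, exposure variation) that the entropy transform
strips while retaining anatomy, which is where its published benefit comes
from. The synthetic images are piecewise constant with independent noise:
there, the entropy output reduces to an outline drawing -- body interiors
and background have the same local distribution shape -- discarding the
fill contrast the network exploits and blurring the few-pixel concavities
that separate adjacent stages. The benefit of entropy preprocessing is a
statement about the nuisance structure of real radiographs, and this
generator deliberately does not simulate that structure (see the preset
descriptions above); extending the generator with structured texture would
be the way to study the effect synthetically, and is left as future work
rather than retrofitted to make the test pass.

## Known limitations

* The generator's morphology ranges are a modeling choice; inter-stage
  geometric variability is not quantified in the literature this package
  operationalizes.
* The rule stager consumes landmarks; automatic landmark detection on real
  radiographs is out of scope.
* Single-channel PNG I/O only (8-bit write); DICOM is out of scope.
* The CNN trains on CPU in single precision; there is no GPU path, no data
  augmentation, and no transfer learning from pretrained networks.
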