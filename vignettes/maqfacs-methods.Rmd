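---
title: "Methods: eigenface-based action-unit recognition for macaque face video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: eigenface-based action-unit recognition for macaque face video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maqfacs)
```

## The problem and the model

Macaque facial behaviour is coded with MaqFACS, an anatomically based scheme
that assigns numerical codes to elemental facial movements (action units,
AUs). Manual coding is slow; this package implements an automatic classifier
for the six AU classes that dominate head-fixed frontal recordings, treated
separately per facial region:

* upper face: `UpperNone` (no coded action), `AU1+2` (brow raiser),
  `AU43_5` (eye closure/blink, merged because the two differ only in
  movement duration);
* lower face: `AU25+26` (lips part + jaw drop), `AU25+26+16` (plus lower
  lip depressor), `AU25+26+18i` (plus true pucker).

The pipeline is classical eigenface ("EigenActions") recognition:

1. **Alignment.** Seven landmarks (four eye corners, two mouth corners,
   mouth centre), annotated once per video on the mean of its neutral
   frames, are mapped by a least-squares affine transform to fixed reference
   fractions of the frame (eye corners at 0.42/0.48/0.52/0.58 w, 0.3 h;
   mouth corners at 0.44/0.56 w, 0.55 h; mouth centre at 0.5 w, 0.5 h). One
   transform per video, applied to every frame.
2. **ROIs and δ-images.** Aligned frames are cropped to rectangular upper-
   and lower-face ROIs. Per video, an "optimal" neutral frame is selected
   and subtracted from every frame, giving signed δ-images that remove
   static appearance (identity, illumination) and keep facial deformation.
3. **Eigenfaces.** δ-images are flattened row-major into an n × p database,
   zero-meaned, and decomposed by snapshot PCA (eigendecomposition of the
   n × n Gram matrix when n < p). Components are unit-normalized and those
   with eigenvalue below 1e-6 are discarded. The feature vector of an image
   is its projection weights onto the leading N components, where N is the
   smallest count whose cumulative explained variance reaches the
   `pcExplVar` target.
4. **Classification.** K-nearest neighbours in the eigenspace (Euclidean or
   cosine distance), or a linear one-vs-one SVM. After zero-meaning and
   unit-normalization, Euclidean distance in this space is monotonically
   related to image correlation, which motivates nearest-neighbour matching.

## Class harmonization

Raw per-frame code sets are harmonized to a single class per region:
unlabelled frames are neutral (`UpperNone` / `LowerNone`); `AU43`, `AU45`
and `AU43_5` all map to `AU43_5`; `AU12` is deleted before matching the
lower-face sets because it is too infrequent in the training corpus to
model; any residual combination maps to a non-target sentinel
(`OtherUpper` / `OtherLower`) that is excluded from training and testing
but retained for behavioural reporting. Multi-unit upper-face frames (e.g.
brow raise together with eye closure) are rare and also map to
`OtherUpper`; the mapping can log them for inspection. The lower-face
neutral is represented as its own `LowerNone` class (rather than folding it
into `OtherLower`) because neutral-frame selection and behavioural
summaries need to distinguish "no action" from "an action we do not
classify".

## Balanced training sets and validation designs

Class frequencies are extremely skewed (neutral dominates), so training
sets are balanced by random undersampling: the smallest class fixes the
per-class size m; every one of its rows is kept and each larger class
contributes a uniform sample without replacement of size m. Several
balanced sets (3–10) are drawn; each is fully determined by `(seed,
set_index)`. Undersampling affects only training pools — test sets always
use all available frames.

Three generalization designs are provided, with per-class inclusion
thresholds that mirror the study protocol:

* within-subject leave-one-video-out (≥ 20 training and ≥ 5 test frames
  per class),
* across-subject leave-one-subject-out (≥ 150 / ≥ 50),
* repeated stratified 80/20 holdout (100 splits; per-class test counts by
  largest-remainder rounding, so the global 20% is hit exactly whenever
  divisible).

Hyperparameters (k = 1..12, `pcExplVar` = 50..95%, metric) are grid
searched; for every balanced set and grid point the eigenfaces are
refitted on the balanced rows inside each partition's training pool, and
the score is the mean over partitions of the average per-class sensitivity
(average TPR), the model-selection criterion. Ties break deterministically:
higher score, then smaller k, smaller `pcExplVar`, Euclidean before cosine,
smaller set index. Results are aggregated per subject (videos averaged
within subject first), then across subjects as mean ± SE.

## Numerical choices

* **Affine estimation.** Seven correspondences over-determine the six
  affine parameters; ordinary least squares gives the unique minimizer for
  non-collinear landmarks and is exact (residual < 1e-9) on
  affine-consistent sets. Collinear sources raise an error.
* **Coordinates and resampling.** 0-based pixel-centre coordinates
  (x = column, y = row, origin top-left). Warping inverse-maps output
  pixels and samples bilinearly with zero fill outside the source; the
  scheme and fill are package choices, documented because they affect
  margins visible after large pose corrections.
* **Optimal neutral frame.** The criterion is unspecified in manual
  practice; here it is the neutral frame L2-closest to the video's mean
  neutral image (ties to the smallest index), with a per-video manual
  override honoured verbatim.
* **Eigen decomposition.** Deterministic symmetric eigendecomposition (no
  iterative solvers). The Gram matrix is divided by n − 1 (unbiased sample
  covariance), pixel values stay on the native 0–255 scale, and the
  eigenvalue cut-off 1e-6 applies on that scale; all three conventions
  matter for reproducing a given component count, so the threshold is
  exposed as configuration. Explained-variance ratios are computed over the
  components surviving the cut-off. Component signs are fixed by making the
  largest-magnitude element positive. Degenerate inputs (constant images;
  fewer than two rows) raise errors rather than returning empty models.
* **KNN tie rules.** Neighbour ties at the k-th radius admit the smaller
  training index; vote ties go to the class with the smaller summed
  distance, then to the fixed class order. This makes predictions exactly
  reproducible across platforms, which the tests verify against a
  brute-force vote.
* **SVM.** Hyperparameters beyond "linear multiclass" are package defaults:
  one-vs-one, cost 1, features standardized by training mean/SD. The fit is
  delegated to e1071/libsvm and is deterministic for a fixed training set.
* **Undefined sensitivities.** A class absent from a test set has undefined
  TPR; it is reported as `NA` and excluded from the average with a warning.
  The inclusion thresholds normally prevent this.

## The synthetic generator

`generate_dataset()` renders schematic frontal faces: a smooth background
blob, brows, eye ellipses, a nose and a mouth, all built from
compact-support quartic bumps so that a deformation touches exactly the
pixels inside its region's ROI (Gaussian tails would leak across the ROI
border and blur region-locality tests). Deformations follow the AU
semantics: brow raise displaces the brow bars upward, eye closure shrinks
the eye aperture toward zero, lips-part/jaw-drop opens the mouth aperture
downward, the lower-lip depressor adds a bar pushed below the mouth, and
the pucker narrows the mouth and adds protrusion shading. All displacement
amplitudes scale with a per-AU pixel magnitude, so magnitude 0 renders
classes identically.

Per subject, deterministic appearance offsets (brightness, brow thickness,
eye aperture, feature contrast) are derived from the seed and subject id;
landmarks stay at the reference fractions, so inter-subject variation is
appearance, not geometry. Per video, one affine pose offset (rotation about
the centre, scale, translation) is drawn and the face is rendered
analytically in posed coordinates — no resampling — which makes the true
landmarks exact and lets alignment tests measure recovery error honestly.
Labels come in contiguous episodes (AU episodes ≥ 3 frames, geometric
lengths with mean 6), with episode draw probabilities length-corrected so
frame-level class frequencies match the configured rates in expectation.
The default frequencies make the neutral class dominant and the brow raiser
rare, the shape seen in spontaneous head-fixed recordings.

What the generator does **not** emulate: 3-D head pose (only affine image
pose), fur texture, illumination changes within a video, occlusion, codec
artifacts, or coder disagreement. Passing the end-to-end tests therefore
shows that the pipeline's stages compose correctly and recover known
structure under controlled variation — not that real-video performance
reaches any particular level.

## Problem sizes used by the tests

The shipped checks run at deliberately small scale so the whole suite stays
fast and deterministic: 64 × 56-pixel frames, 3–4 subjects with 2 videos of
40–120 frames for end-to-end runs (with class frequencies evened out so the
leave-one-subject thresholds of 30/10 training/test frames per class are
met at this scale), 48 × 42-pixel frames over 20 seeds for the
zero-deformation chance control (run with noise SD 4, since at magnitude 0
and zero noise all δ-images are exactly zero and the eigenface fit is —
correctly — degenerate), and 10⁵ Monte-Carlo draws for the random-classifier
chance level. The balanced-set arithmetic is checked at the full published
class counts (1213/19 500/150 000 upper; 310/15 000/15 000 lower), which is
cheap because balancing only touches indices.

## Known limitations

* Landmarks are annotated manually (a file format is provided); there is no
  automatic landmark detector.
* One affine transform per video assumes the head stays fixed within a
  video; slow drift within a video is not corrected.
* The classifier assigns exactly one class per region per frame; genuinely
  mixed upper-face frames fall into the sentinel class and are not scored.
* Eigenface features are global per ROI; they are sensitive to residual
  misalignment in a way localized features would not be.
* The SVM path reuses the KNN feature pipeline; no kernel or cost tuning is
  built in beyond the exposed configuration.
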