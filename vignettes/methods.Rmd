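---
title: "Temporal subtraction of sequential mammograms: models, parameters and design choices"
author: "mammodelta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal subtraction of sequential mammograms: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mammodelta)
```

## The problem

Screening mammography produces, for every participant, a short longitudinal
series of image pairs (cranio-caudal and medio-lateral oblique views). When a
mass is found in a screening round, the two preceding rounds of the same
breast were usually read as normal — yet the tissue change that became the
mass is often already present below the threshold of visual detection.
`mammodelta` implements a pipeline that asks: *given the current and the
prior round, which regions of the current mammogram are likely to present a
mass in the next round?*

The pipeline has two parts.

**Part A — ground truth.** For cases where the most recent ("future") round
contains a biopsy-confirmed mass with an expert outline, the future view is
deformably registered to the current view and the outline is carried through
the deformation. The resulting propagated mask marks, on the current
mammogram, the location where the mass will appear, even though nothing is
visible there. Future images are not used after this step.

**Part B — prediction.** For all cases, the prior round is registered to the
current round and subtracted from it. New bright structure survives the
subtraction; unchanged anatomy cancels. The difference image is enhanced,
thresholded and cleaned morphologically; the surviving connected components
are the candidate regions of interest (ROIs). Each ROI is described by a
98-value feature vector, and a classifier — evaluated under patient-grouped
cross-validation — labels each ROI as a normal interval change or a future
malignancy.

## Registration

Registration uses the classic intensity-driven demons algorithm: a dense
displacement field is accumulated from the optical-flow-like update

$$\delta u = \frac{(f - m \circ \varphi)\,\nabla f}
                 {\lVert \nabla f \rVert^2 + (f - m \circ \varphi)^2},$$

with the field smoothed by a Gaussian after every iteration (diffusion-like
regularization) and a three-level coarse-to-fine pyramid. The current round
is always the fixed image $f$; the future (Part A) or prior (Part B) round
is the moving image $m$, so both deformation fields live on the current
grid and a single convention covers mask propagation and subtraction.

Defaults: 3 levels, 50/30/10 iterations coarse to fine, smoothing sigma
2 px, and a patience-based stopping rule (a level stops after five
iterations without a relative sum-of-squared-differences improvement of at
least `convergence_tol`; the raw per-iteration SSD oscillates near
convergence, so a single non-improving step must not stop the
optimization). There is no random initialization, so registration is
deterministic. If the final field fails to reduce SSD against the unwarped
baseline, the zero field is returned with a warning — alignment is never
made worse.

Masks are propagated by warping the 0/1 mask as a float image and
re-thresholding at 0.5, which approximately preserves area under smooth
fields. An empty propagated mask (mass carried out of frame) is flagged for
review rather than silently dropped.

## Subtraction and enhancement

The registered prior is subtracted from the current image and negative
differences are clipped: a developing mass is new *bright* structure, and
disappearing dark structure is not a candidate. (A `keep_signed` switch
retains the signed difference for research use.) The difference is then
unsharp-masked, `out = img + amount * (img - blur(img, radius))` with
radius 5 px and amount 1 by default, to lift the high spatial frequencies
that subtle new structure occupies, and clipped to [0, 1].

The contrast ratio used to quantify the benefit of subtraction is the mean
intensity inside a lesion mask over the mean intensity of a surrounding
10 px annulus; on the synthetic cohort the ratio at the true mass location
rises after subtraction, in the direction the method predicts.

## Segmentation

Three steps, matching the printed radii exactly:

1. **Thresholding** at a fixed value (default 0.06 on the [0, 1]-clipped
   enhanced difference) eliminates low-intensity normal areas. A
   `select_threshold()` helper scores candidate thresholds — quantiles of
   the pooled nonzero histogram — by a detection Jaccard
   (TP / (TP + FP + FN) over ground-truth mass components and false ROIs),
   with ties resolved toward the lower threshold; the pipeline accepts
   `threshold = "auto"` to use it.
2. **Morphology**: disk erosion of radius 2 px removes isolated pixels from
   registration misalignment, then disk closing of radius 10 px merges the
   constituents of one mass. Images are padded so the operations follow
   ideal set-theoretic morphology with background outside the frame; the
   test suite checks agreement with a brute-force shift-based oracle.
3. **Periphery removal**: components intersecting a 15 px band inside the
   breast border (or lying outside the breast) are deleted — skin-line
   regions cannot be masses.

Components are 8-connected; components smaller than 9 px² are dropped. An
ROI is labeled a future malignancy when at least 25% of its area overlaps
the propagated ground-truth mask.

## Features

Each ROI yields 98 named values in a fixed registry:

* **15 shape features** — areas (raw, filled, convex), perimeter, the
  inertia-ellipse axes and orientation, eccentricity, solidity, extent,
  Euler number, circularity $4\pi A / P^2$, compactness $P^2 / (4\pi A)$
  and the major/minor axis ratio. The perimeter is measured on the
  0.5-level marching-squares contour after two corner-cutting passes, which
  removes the staircase bias (a digital disk would otherwise read about 7%
  long and push circularity far from 1).
* **9 intensity / first-order statistics** — mean, max, min, STD, variance,
  smoothness $1 - 1/(1+\sigma^2)$, skewness, kurtosis and the Shannon
  entropy of a 64-bin histogram.
* **72 GLCM texture values** — symmetric normalized co-occurrence matrices
  of the bounding-box patch quantized to 32 gray levels over its own range
  (so texture is invariant to intensity offsets), at offsets D1 = 5,
  D2 = 15, D3 = 25 px and angles 0/45/90/135 degrees. For each offset and
  each base feature (contrast, correlation, energy, homogeneity) the four
  per-angle values are reported with their mean and STD: 24 values per
  offset. A constant patch takes correlation 0 by the documented
  degenerate-variance rule; patches smaller than an offset are edge-padded
  and flagged.
* **2 epidemiological values** — age in years and BI-RADS density a-d
  encoded 1-4.

The published material names the total (98) and roughly a quarter of the
individual features; the remaining complement of this registry is a
reconstruction that reproduces the total and every published name, and is
documented as such.

## Feature selection

Eight ranking techniques (Welch t statistic, mutual-information mRMR,
impurity importances from extra trees / random forests / gradient-boosted
trees, the univariate ANOVA-F filter, and sequential forward / backward
wrappers around a 5-fold cross-validated linear discriminant) produce
top-k lists (k = 25 by default). The final subset keeps any feature present
in at least `min_votes` lists. With the eight published rankings (shipped
as a plain-text fixture) `min_votes = 4` returns exactly the published
14-feature selection, and no feature outside it reaches four votes; 4 of 8
therefore ships as the default. The published-table transcription has some
row-alignment ambiguity in its source material; the fixture resolves it
conservatively and the merge is robust to those choices because membership,
not rank, drives the vote.

## Class balancing and evaluation

ROI labels are heavily imbalanced (tens of true-mass ROIs against
thousands of clutter ROIs). Training folds are balanced with ADASYN:
synthetic minority samples are allotted per minority point in proportion to
the majority fraction among its 5 nearest neighbours and generated by
convex interpolation toward random minority neighbours — every synthetic
point lies on a segment between two minority originals, which the tests
verify geometrically. Test folds are never augmented.

Cross-validation is grouped by patient: leave-one-patient-out by default,
or per-patient stratified k-fold (k = 5 or 15). Per fold, standardization,
ADASYN, optional per-fold feature selection and classifier fitting see
training patients only; an audit mode records which patients reached each
stage so the absence of leakage is asserted by a test rather than assumed.

Classifier families: LDA, QDA, naive Bayes, k-NN (k in {1,3,5,7,9,11},
ties among the k votes broken by the single nearest neighbour), SVM
(linear / polynomial / RBF, decision values calibrated by Platt scaling),
random forest, extra trees, gradient boosting, AdaBoost (SAMME with
decision stumps), a BFGS-trained multilayer perceptron, and a
single-hidden-layer network with ReLU hidden units and softmax output
trained by mini-batch Adam (batch 128, learning rate 1e-4, 100 epochs).
The default ensemble soft-votes LDA, k-NN (k = 9), polynomial SVM, naive
Bayes and extra trees; hard voting breaks ties toward the positive class,
prioritizing sensitivity.

Metrics are pooled over folds: sensitivity, specificity and accuracy from
the confusion counts; AUC by the Mann-Whitney rank statistic on the pooled
scores; false positives per subtraction image; and per-patient sensitivity
(a malignant patient counts as detected when any of their true-mass ROIs,
in either view, is flagged). Classifier pairs are compared with the
continuity-corrected McNemar test on discordant pairs, applied pairwise
with Bonferroni adjustment as the multi-classifier form.

## The synthetic cohort

Clinical three-round series with biopsy-confirmed outcomes are not
publicly available, so the package ships a generator that emulates the
study population structure: 75 cases (34 malignant / 41 normal), ages
uniform in 46-79, BI-RADS densities drawn 13/29/29/4 (a/b/c/d), two views
per case, three rounds per view at 256 x 256 pixels.

Per view, a smooth multi-scale background texture (Gaussian fields at
sigma 32/12/4 px, dominated by the parenchyma-scale components) fills a
half-ellipse breast support (the MLO view adds a pectoral wedge). The
prior and future rounds are independent smooth deformations (amplitude up
to 8 px, smoothness 40 px) of the current-round anatomy, emulating
compression differences between visits. Interval change is modelled by
bright Gaussian clutter blobs, mostly new in the current round; malignant
cases additionally receive a flat-top (super-Gaussian) mass in the future
round and a faint precursor — 0.15 of the mass amplitude — at the
deformation-consistent location in the current round. Future masks are the
exact injected supports.

Design notes, fixed once and not revisited:

* The precursor amplitude must exceed the local texture variation within
  the registration's reach; an intensity-driven registration can otherwise
  "absorb" the precursor by resampling nearby bright prior texture, which
  is also why masses use a flat-top profile (no interior gradient for the
  demons force to act on).
* Clutter blobs are placed with a minimum 22 px spacing and kept clear of
  the mass site; the 10 px closing would otherwise fuse unrelated changes
  into giant regions. At this working resolution the closing makes
  candidate regions collide geometrically, which caps the density near
  ~25 ROIs per image — about half the density the original study reports
  at native detector resolution. This is a resolution-scaling effect, not
  a free parameter.
* All randomness derives from one master seed; every case is a pure
  function of (seed, patient index).

What the generator does **not** emulate: X-ray physics, scanner artifacts,
pectoral-muscle texture, benign-vs-malignant morphology differences, and
reader variability in the expert outlines. Passing the synthetic benchmark
therefore demonstrates that the pipeline's machinery — registration,
subtraction, segmentation, features, grouped evaluation — is correct and
leak-free under controlled conditions; it does not certify clinical
performance.

## Numerical choices and degenerate inputs

* Working intensities are floating point in [0, 1]; source bit depth is
  metadata. Coordinates are (row, col), 0-based at serialization
  boundaries.
* A constant image normalizes to all zeros, passes CLAHE unchanged, and
  yields entropy 0 and smoothness 0.
* CLAHE pads by edge replication up to a tile multiple and crops back;
  its clip limit is expressed as a fraction of the uniform histogram
  height.
* Features that would divide by zero (correlation of a constant patch,
  axis ratio of a degenerate region) take documented finite values
  (0, and major/max(minor, 0.5)).
* Fold-constant feature columns are dropped per fold (they carry no
  information and break the discriminant families); QDA receives a
  deterministic 1e-7 jitter to keep class covariances nonsingular.
* Problem sizes in the shipped tests: registration recovery uses twenty
  128 x 128 pairs; the synthetic benchmark runs the full 75-patient
  cohort at 256 x 256; module tests use 64-96 px toys. These sizes keep
  the whole suite reproducible on a laptop while exercising every stage
  at realistic scale.

## Known limitations

* The demons variant is the classic fixed-image-gradient form; diffeo-
  morphic or log-domain variants are out of scope (the configuration
  object isolates them behind one interface if ever added).
* Only temporal (not bilateral) subtraction is implemented.
* DICOM input is not supported in this build; images are 8/16-bit
  PNG/TIFF.
* The exact identity of the unnamed features beyond the published names,
  the published majority threshold, and the exact "extended" McNemar
  formulation are reconstructions; each is documented where it is used
  and fixed by a test where the published material constrains it.
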