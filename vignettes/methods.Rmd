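---
title: "Segmenting and classifying lumbar vertebral bodies with vbseg"
author: "vbseg authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting and classifying lumbar vertebral bodies with vbseg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vbseg)
```

## The problem

Vertebral compression fractures (VCFs) show up in a sagittal spine image as
a partial collapse of the vertebral body (VB): the anterior (front) height
of the VB drops, its superior boundary deforms, and the overall silhouette
shifts from a rounded rectangle towards a wedge. `vbseg` implements a
classical (non-deep-learning) pipeline that takes a 2-D grayscale sagittal
image, isolates the lumbar vertebral bodies L1–L5, summarizes each as a
compact shape/intensity feature vector, and classifies each VB as normal or
fractured with k-nearest neighbours or a linear support vector machine. The
stages are exposed as ordinary functions, so each is testable against
analytic ground truth, and a phantom generator provides a fully synthetic
test bed with exact masks and labels.

## The phantom: what it emulates, and what it does not

Clinical datasets of this kind are small (tens of patients, hundreds of
VBs) and rarely redistributable, so the package ships a generator rather
than data. `generate_case()` draws a vertical stack of bright
rounded-rectangular VBs on a dark background and adds, in order:

1. **Anterior wedge compression** for fractured levels: column heights are
   scaled by a factor rising linearly from `1 - height_loss_fraction` at
   the anterior (left) edge to 1 at the posterior edge, with the inferior
   boundary fixed — the classical wedge morphology. The collapsed superior
   boundary is additionally perturbed by smoothed Gaussian jitter of
   amplitude `boundary_irregularity` (pixels).
2. **A smooth multiplicative bias field** in
   `[1 - bias_amplitude, 1 + bias_amplitude]`, built from two separable
   low-frequency cosine terms with random phases — the kind of slow
   inhomogeneity histogram equalization is meant to mitigate.
3. **Additive i.i.d. Gaussian noise** (`noise_sd`), then clipping to the
   8-bit range.

Defaults are a 256×256 image with five 28×44 px VBs separated by 10 px
gaps, foreground mean 180, background mean 40, `noise_sd = 5`,
`bias_amplitude = 0.1`, `height_loss_fraction = 0.4`: a desk-scale, visually
plausible lumbar stack whose contrast regime (bright marrow on dark
background) mimics a T1-weighted appearance. `generate_dataset()` draws
per-vertebra fracture labels i.i.d. Bernoulli; its default of 63 cases × 5
VBs = 315 vertebrae mirrors the scale of the published clinical studies
this kind of pipeline is evaluated on, and a prevalence around 0.3
reproduces the characteristic class imbalance.

The phantom deliberately does **not** model MR physics (no Rician noise, no
pulse sequences), 3-D anatomy, posterior elements, discs, or the textural
differences between benign and malignant fractures. Consequently, passing
the synthetic end-to-end checks shows the pipeline's machinery is sound and
that wedge-type shape change is detectable at realistic noise — it does not
certify clinical performance.

## Preprocessing

`spatial_filter()` applies a k×k neighbourhood operator (median, mean, or
identity) with symmetric reflect padding; the 3×3 median is the default
smoother. `equalize_histogram()` is the textbook global mapping: with
`h(j)` the gray-level counts, `CDF(i) = sum_{j<=i} h(j)`,
`CDF_norm = CDF / N`, each level maps to
`round(CDF_norm(i) * (L - 1))` with round-half-up (fixing the `127.5`
ambiguity deterministically). The mapping is monotone, and re-equalizing
moves no pixel by more than one level. A tiled adaptive variant
(`equalize_adaptive()`) is available behind a flag but is not part of the
default pipeline, which follows the global formulation.

Pipeline order is smoothing **then** equalization: median smoothing first
prevents isolated noise spikes from distorting the CDF.

**Where the threshold is estimated.** Histogram equalization flattens the
gray-level histogram *by construction*. On an image whose content is
essentially two intensity populations with a dominant background — exactly
the phantom's regime — the equalized histogram is near-uniform, and a
between-class-variance (Otsu) threshold on it degenerates towards the
median gray level, splitting the background instead of separating bone
from background. The default pipeline therefore estimates the Otsu
threshold on the smoothed, *pre-equalization* image
(`threshold_on = "smoothed"` in `pipeline_config()`), while the equalized
image is retained for the grayscale feature block, where its
bias-mitigating effect is wanted. `threshold_on = "equalized"` restores
thresholding after equalization for images with richer intensity content.

## Segmentation

`segment_pipeline()` chains: binarization (Otsu by default) → morphological
closing (dilation then erosion, disk of radius 2) → hole filling → removal
of border-touching components → island filtering → centroid-x alignment
filtering → per-component convex hull → top-to-bottom labelling L1–L5.

Conventions that matter:

* **Connectivity** is 8 for foreground and 4 for background (holes), the
  Jordan-consistent pairing.
* **Erosion** uses the standard fit condition (the structuring element must
  lie entirely in the foreground), with out-of-image pixels counted as
  background. Under this boundary convention closing is extensive only for
  content whose dilation stays inside the image — true for the phantom,
  whose masks keep a guaranteed border margin.
* **Island filtering** removes components smaller than 5% of the largest;
  **centroid filtering** keeps components whose centroid x lies within
  0.15 × image width of the median centroid-x. Both thresholds are relative
  so they are invariant to field-of-view changes; neither is given
  numerically in the source literature, so both are package choices and
  both are configurable.
* **Convex-hull regularization** replaces each component with the pixels
  inside the convex hull of its pixel centres. Fracture fragmentation and
  boundary collapse produce concavities; the hull restores a compact,
  slightly conservative VB silhouette.

## Shape features

For each labelled region `extract_features()` computes: centroid;
population covariance of the foreground pixel coordinates with closed-form
eigenvalues; **eccentricity** `E = lambda2 / lambda1` (1 for rotationally
symmetric shapes, towards 0 with elongation — note this convention differs
from the conic-section eccentricity); the axis of least inertia (leading
eigenvector angle in `[0, pi)`); **rectangularity** = pixel area over the
minimum-*area* bounding rectangle, found by rotating calipers over the
convex hull ("minimum bounding rectangle" is otherwise ambiguous; the
area-minimal one is orientation-free and deterministic); **convexity** =
hull perimeter / contour perimeter; the **Euler number** (8-connected
components minus 4-connected holes); x/y **projection profiles** over the
bounding box; **bending energy** (below); and in-mask intensity mean, sd,
skewness and kurtosis as the grayscale block (the source literature's
"textural elements" are never specified; intensity moments are this
package's concrete choice, and co-occurrence texture is deliberately out of
scope).

**Contours.** Region contours are the 0.5-level marching-squares
iso-boundary of the mask, a sub-pixel closed polygon traversed clockwise
(in image coordinates, y down) from the topmost-then-leftmost vertex. Using
the iso-boundary rather than pixel centres keeps rectangularity at exactly
1 for solid rectangles and ≤ 1 elsewhere.

**Bending energy** is the mean squared curvature along the closed contour.
The contour is resampled to `n_samples = 128` equal-arc-length points, the
coordinate functions are Fourier-truncated at `n_harmonics = 16`, and
curvature is evaluated analytically from the Fourier derivatives. The
truncation is what makes the statistic usable on rasterized masks: raw
staircase boundaries have unbounded curvature, while 16 harmonics preserve
wedge-scale shape. A circle of radius r gives `1/r²` within a few percent
at desk scale; both knobs are configurable, and small shapes (radius below
roughly 20 px at the defaults) remain rasterization-dominated.

**Vectorization.** Profiles are variable-length, so the classifier vector
carries four summaries per axis (length, max, mean, coefficient of
variation). The full fixed order is documented by `feature_vector()`'s
names: area, eccentricity, rectangularity, convexity, Euler number,
bending energy, the eight profile summaries, then the four intensity
moments. Blocks can be switched off to make the active feature subset
explicit and reportable.

## Class balancing

Fractured VBs are the minority class. `smote()` implements the classical
feature-space interpolation: a synthetic minority row is
`x + u (x_n - x)` with `x_n` one of the `k = 5` nearest minority
neighbours and `u ~ U(0, 1)`. Although the surrounding literature
sometimes speaks of generating synthetic *images*, the cited algorithm is
defined in feature space, and that is what is implemented; pixelwise image
interpolation is not SMOTE. `rotate_augment()` provides the companion
image-space augmentation (rotations within ±15°, bilinear for images,
nearest-neighbour for masks).

Balancing is applied **inside each training split only**, after the split
is fixed. Balancing before splitting would leak interpolated copies of
test-adjacent minority rows into training and inflate every test metric;
the grid protocol enforces the safe ordering.

## Classification

`knn_predict()` is exact brute-force KNN: Euclidean distances, majority
vote, posterior = neighbour class fraction; distance ties break by lower
training-row index and odd k avoids vote ties. `svm_train()` minimizes the
primal `0.5 ||w||² + C Σ hinge` through its dual with sequential minimal
optimization (maximal-violating-pair selection, deterministic); the margin
formulation alone would be the hard-margin classifier, and tuning C is only
meaningful in the soft-margin form, so soft margin is what is implemented.
Features are z-scored with training-split statistics (both classifiers are
scale-sensitive). A decision value of exactly zero goes to the positive
(fractured) class. `svm_tune_C()` offers 5-fold CV over
`{0.01, 0.1, 1, 10, 100}`; the grid protocol uses a fixed `C = 1` by
default so that its runtime stays proportional to the split grid.

`grid_search()` evaluates KNN at k ∈ {3, 5, 7, 9, 11} and the linear SVM at
stratified train:test splits 30:70 … 80:20 (seeded, SMOTE on the training
side), reporting accuracy, precision, recall and F-measure per split plus
an Average row — the standard benchmark table layout. Splits are
per-vertebra; a per-patient grouping is a known limitation (vertebrae of
one subject are correlated), noted below.

## Evaluation and model comparison

Segmentation is scored per VB by accuracy, sensitivity, Dice and Jaccard
(with `DSC = 2J/(1+J)` as an internal consistency check);
`leave_eleven_out_cv()` partitions cases sequentially into disjoint test
folds of 11 with the remainder in the last fold (63 cases → 11, 11, 11, 11,
11, 8). Zero-denominator metrics return 0 with a `degenerate` flag instead
of erroring, so batch evaluation survives empty predictions.

`paired_t_test()` wraps the two-sided paired t-test.
`wilcoxon_signed_rank_exact()` computes the exact two-sided signed-rank
test by enumerating the null distribution of the positive-rank sum over
all 2^n sign assignments via a generating-function recursion; tied absolute
differences get average ranks (doubled internally to stay integral), zero
differences are dropped with a warning, and the reported `W` is the
smaller rank sum. With six one-signed differences this yields the floor
`p = 2/64 = 0.03125` — the smallest two-sided p attainable at n = 6, which
is why a 6-split comparison can be "maximally significant" and still carry
that seemingly large p. The exact route is used because at n = 6 the
normal approximation is meaningless. No multiple-testing correction is
applied across the five k-comparisons, matching the benchmark protocol the
tables reproduce.

## Numerical choices and degenerate inputs

* Round-half-up for all image-intensity rounding.
* Otsu refuses single-level histograms; `principal_axes()` refuses regions
  under 2 pixels; contour code refuses self-intersecting or sub-8-point
  contours; `filter_components()` and `label_vertebrae()` refuse empty
  masks — each with a named error.
* SMO stops when the maximal KKT violation falls under `1e-5`, which lands
  the primal objective within `1e-3` relative of an independent solver on
  the problem sizes used here.
* All randomness flows from one master seed through deterministic
  per-stage sub-seeds (`derive_seed`), so any stage can be re-run in
  isolation and the full pipeline is bit-reproducible.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run the full pipeline at 63 cases
× 5 VBs (`noise_sd = 5`, `bias_amplitude = 0.1`, prevalence 0.3, height
loss 0.4), the scale the package's defaults are aimed at; property checks
use masks up to 20×20 against brute-force oracles and analytic shapes
(disks, ellipses, triangles) for the descriptor identities. On one CPU the
whole suite runs in about a minute.

## Known limitations

* Per-vertebra (not per-patient) splits are the default; correlated VBs of
  one subject can appear on both sides of a split.
* The phantom's separability is generous: at the default geometry the
  wedge deformation shifts eccentricity and rectangularity by several
  pooled standard deviations, so classifier accuracies near 100% on the
  phantom say little about clinical discrimination.
* Segmentation assumes a single vertical stack of bright VBs; no disc,
  canal or posterior-element modelling, and no 3-D support.
* DICOM input is not supported (PNG/TIFF only).

## A worked example

```{r example, eval = FALSE}
library(vbseg)
cfg <- pipeline_config(n_cases = 63, fracture_prevalence = 0.3, seed = 11,
                       k_values = c(3L, 11L), train_fractions = c(0.5, 0.8))
rep <- run_pipeline(cfg)
rep$segmentation$mean_dice      # mean per-VB Dice vs ground truth
rep$tables$svm                  # per-split SVM metrics with Average row
rep$comparison                  # paired t + exact Wilcoxon vs the KNN arms
```
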