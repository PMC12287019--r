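# vbseg

Automated segmentation and fracture classification of lumbar vertebral
bodies (L1–L5) in 2-D sagittal grayscale images, for researchers building
or benchmarking classical (non-deep-learning) vertebral-fracture
decision-support pipelines.

A vertebral compression fracture partially collapses the vertebral body
(VB): anterior height drops and the silhouette shifts from a rounded
rectangle towards a wedge. `vbseg` detects that shift with a fully
inspectable pipeline:

1. **Preprocess** — neighbourhood spatial filtering `g(x,y) = T[f(x,y)]`
   (3×3 median by default) and global histogram equalization via the CDF
   mapping `I_new(i) = round(CDF_norm(i) · (L−1))`.
2. **Segment** — Otsu thresholding; binary morphology with
   `A ⊕ B = {z : (B̂)_z ∩ A ≠ ∅}` (dilation) and its fit-condition dual
   (erosion); hole filling; border clearing; island and centroid-alignment
   filtering; per-component convex-hull regularization; top-to-bottom
   labelling L1–L5.
3. **Describe** — per-VB shape features: eccentricity `E = λ₂/λ₁` from the
   pixel-covariance eigenvalues, rectangularity `A_S / A_R` against the
   minimum-area bounding rectangle (rotating calipers), convexity
   `O_hull / O`, Euler number `S − N`, projection profiles
   `Pro_x(i) = Σ_j f(i,j)`, Fourier-smoothed contour bending energy
   `BE = (1/N) Σ K(s)²`, and in-mask intensity moments.
4. **Balance** — SMOTE (`x + u(x_n − x)`, u ~ U(0,1), k = 5 minority
   neighbours) applied inside training splits only, plus ±15° rotation
   augmentation.
5. **Classify & evaluate** — Euclidean KNN (k = 3…11) and a linear
   soft-margin SVM (`min ½‖w‖² + C Σ hinge`, SMO solver) over stratified
   train:test splits 30:70…80:20; accuracy/precision/recall/F-measure and
   Dice/Jaccard metrics; paired t and **exact** Wilcoxon signed-rank
   comparison between classifier arms.

Because clinical spine MRI is rarely redistributable, the package includes
a **phantom generator**: synthetic sagittal spines with anterior-wedge
fractures, smooth intensity bias, Gaussian noise, and exact ground-truth
masks and labels, defaulting to the 63-case / 315-VB scale typical of
clinical studies of this kind.

## Worked example

```r
library(vbseg)

case     <- generate_case(phantom_spec(fracture_levels = c(2, 4), seed = 7))
smoothed <- spatial_filter(case$image, "median", 3)
regions  <- segment_pipeline(smoothed, seg_config())
eq       <- equalize_histogram(smoothed)$image
for (r in regions) {
  f <- extract_features(eq, r)
  cat(sprintf("%s  label=%d  dice=%5.2f  E=%.3f  rect=%.3f  conv=%.3f\n",
              r$level, case$labels[[r$level]],
              dice(r$mask, case$truth_masks[[r$level]]),
              f$eccentricity, f$rectangularity, f$convexity))
}
#> L1  label=0  dice=99.75  E=0.406  rect=0.966  conv=0.984
#> L2  label=1  dice=98.71  E=0.287  rect=0.853  conv=0.972
#> L3  label=0  dice=99.75  E=0.406  rect=0.966  conv=0.984
#> L4  label=1  dice=98.46  E=0.287  rect=0.827  conv=0.968
#> L5  label=0  dice=99.75  E=0.406  rect=0.966  conv=0.984
```

Segmentation recovers every VB with Dice above 98%, and the two fractured
levels (label 1) stand out exactly as the wedge model predicts: lower
eccentricity (more elongated silhouette after anterior height loss) and
lower rectangularity (the wedge fills its minimum bounding rectangle less
completely).

The statistical comparison tools work directly on per-split accuracy
vectors, e.g. on the published benchmark tables shipped with the package:

```r
ref  <- reference_metrics()
knn3 <- ref$accuracy[ref$classifier == "knn" & ref$param == 3]
svm  <- ref$accuracy[ref$classifier == "svm"]
compare_classifiers(list(k3 = knn3), svm)
#>   comparison         t        t_p W     w_p n
#> 1  k3 vs svm -3.667485 0.01448131 0 0.03125 6
```

The negative t says the SVM arm is more accurate on matched splits; W = 0
with p = 0.03125 is the exact signed-rank floor at n = 6 splits (all six
differences share one sign).

`run_pipeline(pipeline_config(...))` chains everything — phantom,
preprocessing, segmentation, features, SMOTE-balanced grid search,
comparison — under a single seed; `inst/exec/vbseg` exposes the same
stages as shell subcommands (`phantom`, `preprocess`, `segment`,
`pipeline`, `compare`).

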