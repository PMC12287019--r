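Package: vbseg
Title: Segmentation and Fracture Classification of Lumbar Vertebral Bodies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An automated pipeline for segmenting lumbar vertebral bodies
    (L1-L5) in 2-D sagittal grayscale images and classifying each as normal
    or fractured. Includes global histogram equalization and neighborhood
    spatial filtering, binary morphology (dilation, erosion, hole filling,
    border clearing) with convex-hull boundary regularization, a shape
    feature set (eccentricity from pixel-covariance eigenvalues,
    rectangularity against the minimum-area bounding rectangle, convexity,
    Euler number, projection profiles, contour bending energy), SMOTE class
    balancing, k-nearest-neighbour and linear soft-margin SVM classifiers
    with a split/hyperparameter grid protocol, segmentation and
    classification metrics, and paired t / exact Wilcoxon signed-rank model
    comparison. A built-in phantom generator produces synthetic sagittal
    spine images with wedge-compression fractures, intensity inhomogeneity,
    noise and exact ground-truth masks, so the whole pipeline is exercisable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    utils,
    tools,
    igraph,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    e1071,
    tiff,
    optparse
Config/testthat/edition: 3
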