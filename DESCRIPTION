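Package: fibersim
Title: Simulation of White-Matter Fiber Bundles and Evaluation of Fiber
    Clustering Algorithms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Generates realistic synthetic white-matter fiber bundles from a
    tubular spline model: a bundle centroid, five circular cross-sections with
    configurable radii, and fourth-order spline fibers built from control
    points drawn inside the tube, with optional Gaussian dispersion at the
    bundle ends. Builds whole-brain ground-truth tractography datasets with
    known per-fiber bundle labels and a crossing-bundle registry, reads and
    writes the BrainVISA bundles/bundlesdata streamline format, and provides
    streamline and bundle similarity metrics (maximum-Euclidean flip
    distance, inter-bundle distance, intersection percentage) plus the
    cluster-evaluation metrics (Overlap Score, Precision/Recall/F-measure,
    clustering-wise Sensitivity/PPV/Accuracy, Maximum Matching Ratio) needed
    to benchmark fiber clustering algorithms, together with a built-in
    QuickBundles baseline and an input-permutation robustness harness.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
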