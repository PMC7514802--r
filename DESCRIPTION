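Package: whaleseg
Title: Multilevel Image Thresholding with a Hybrid Whale Optimization-Differential Evolution Algorithm
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multilevel thresholding of 8-bit grayscale and RGB images by
    maximizing Kapur's entropy (or, alternatively, Otsu's between-class
    variance) with a hybrid whale optimization-differential evolution (WOA-DE)
    metaheuristic. Agents with above-average fitness take differential
    evolution steps to refine promising regions while the rest follow whale
    optimization moves, balancing exploitation and exploration. Includes an
    exhaustive-search oracle for small threshold counts, image quality metrics
    (PSNR, SSIM, FSIM with log-Gabor phase congruency), Wilcoxon rank-sum and
    Friedman tests for algorithm comparison, a synthetic multimodal-image
    generator with Gaussian noise corruption, and a reproducible repeated-run
    experiment harness.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    EBImage,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: Segmentation, Visualization
RoxygenNote: 7.3.3
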