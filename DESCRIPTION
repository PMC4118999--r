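Package: gelclust
Title: Clustering of Two-Dimensional Electrophoresis Gels from Binary Spot Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for the gel-to-cluster analysis of two-dimensional
    electrophoresis (2DE) experiments. Detects protein spots on grayscale gel
    images with a scale-normalized Laplacian-of-Gaussian blob detector,
    matches spot lists to a master gel, assembles binary presence/absence and
    normalized-intensity matrices, quantifies replicate reproducibility
    (Pearson correlation, Q-Q agreement, per-spot coefficient of variation,
    intensity-class histograms, consensus counts), clusters gels by Ward's
    method on Hamming distances, compares partitions with the adjusted Rand
    index, and calls cluster-specific and differentially intense spots with
    Bonferroni correction. A synthetic-data module generates gel images,
    spot lists and binary matrices with planted cluster structure so the
    whole pipeline can be exercised and benchmarked without raw gel scans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    withr,
    EBImage,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    mclust,
    ape,
    jsonlite,
    optparse
Config/testthat/edition: 3
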