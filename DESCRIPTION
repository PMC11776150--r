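Package: scaleleveler
Title: Detection and Correction of Per-Sample Scale Distortion in RNA-Seq
    Expression Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and corrects per-sample, expression-level-dependent scale
    distortions in bulk RNA-seq expression matrices on the log2 scale. Provides
    block-averaging diagnostics over mean-expression-sorted genes, a per-sample
    multiplicative shift correction, a local-leveling transform (a per-sample
    polynomial in each gene's mean expression, fitted by weighted block-averaged
    regression), and a nonlinear rescaling transform (a per-sample polynomial in
    the sample's own measured values, fitted by unweighted block-averaged
    regression). Includes a synthetic-data generator with known ground truth, a
    spiking framework that injects controlled differential expression into real
    or simulated data, and resampling-based evaluation of t-test sensitivity via
    complementary CDF and averaged ROC ensembles with percentile bands, multigene
    convolution tests, single-patient tests, and gene-gene correlation
    distribution comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
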