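Package: tapcnv
Title: Joint Depth and Allele-Frequency Copy-Number Calling for Targeted
    Single-Cell DNA Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Single-cell copy-number inference for targeted DNA amplicon
    panels (Tapestri-style data). Implements a per-chromosome hidden Markov
    model that jointly models reference-normalized read depth and B-allele
    frequency, marginalizing over allele-copy genotypes at each amplicon,
    with Baum-Welch parameter estimation and Viterbi decoding; a depth-only
    baseline caller that fits per-probe Weibull distributions on reference
    cells and classifies chromosome-level medians with a Gaussian mixture;
    a simulator producing Tapestri-like count and allele-frequency matrices
    with known ground truth; and evaluation utilities (confusion matrices,
    macro-F1, balanced accuracy, alteration detection metrics).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    fitdistrplus,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
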