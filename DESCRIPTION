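Package: podquant
Title: Patch-Based Convolutional Detection and Counting of Arabidopsis Siliques
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Two-phase fruit quantification for images of mature Arabidopsis
    inflorescences on a white background. Phase one classifies 32x32 image
    patches into four structural classes (silique base, silique body, stem,
    silique tip) with convolutional neural networks (a LeNet baseline and a
    DenseNet with three dense blocks), trained from sparse point annotations.
    Phase two tiles whole images with 50 percent overlap, fuses the
    overlapping patch predictions into a sub-patch label image by majority
    vote, assembles tip-body-base chains into silique objects, splits
    overlapping fruit pairs with an angle test on base-to-tip vectors, and
    reports per-image counts and length statistics. A parametric synthetic
    inflorescence generator with complete ground truth makes every stage
    testable without scanner data. Network layers are implemented in the
    package (single-precision im2col convolution via 'RcppArmadillo').
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
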