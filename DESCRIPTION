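Package: retseg
Title: Retinal Vessel Segmentation with an Unfolded Kernel-Estimation
    Attention U-Net
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Patch-based segmentation of blood vessels in colour fundus
    photographs.  Implements a U-Net backbone whose convolution blocks are
    densely connected dropout blocks, with atrous (dilated) channel attention
    in the encoder, unfolded deep kernel-estimation (UDKE) refinement blocks
    in the decoder, and a multiheaded attention head whose per-level feature
    attention modules produce refined maps that are averaged into the final
    probability map.  The network, its reverse-mode gradients and the Adam
    optimiser are implemented in R on top of small C++ image-to-column
    kernels.  Ships a synthetic fundus phantom generator with exact vessel
    and field-of-view ground truth, the standard fundus preprocessing chain
    (green-channel extraction, z-score normalisation, CLAHE, gamma
    correction), overlapped patch extraction with mean stitching, a
    deep-supervision cross-entropy objective, and the usual confusion-matrix
    metric suite with ROC-AUC and the Wilcoxon rank-sum test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    jsonlite,
    tibble,
    generics,
    ggplot2,
    EBImage,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
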