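Package: nutnet
Title: GAN-Augmented Atrous-Context Convolutional Classification of Nut Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An end-to-end, fully reproducible pipeline for multi-class nut image
    classification: stratified dataset management with strict test isolation,
    21-fold geometric augmentation (flips and rotations), a classical feature
    filter bank (luminance grayscale, Sobel, Canny, Harris corner keypoints and
    the derived corner-keypoint-featured rendering, kernel isolation), per-class
    deep convolutional generative adversarial networks for synthetic images, an
    atrous (dilated) convolutional classifier with pre- and post-context blocks,
    and an evaluation harness (confusion matrices, macro metrics, stratified
    k-fold cross-validation, paired t-tests, ablation grids). Includes a
    deterministic synthetic fixture generator so the whole pipeline runs at desk
    scale with no external data. The neural-network layers (dilated and
    transposed convolutions, batch and instance normalisation, AdamW with cosine
    annealing) are implemented in base R with hand-derived backpropagation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
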