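Package: hsal
Title: Active Learning with Pseudo-Labeling and Augmentation Pools for
    Hyperspectral Image Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Pool-based active learning for multichannel (hyperspectral)
    image classification under a manual-annotation budget. Implements the
    three classical uncertainty-sampling acquisition criteria (least
    confidence, margin, entropy) as certainty scores, a pseudo-labeling
    curriculum with a growing pseudo-label fraction, and an augmentation-aware
    image pool that turns the flipped/rotated variants of an annotated sample
    into free labels. Ships the full preprocessing chain for hyperspectral
    cubes (spectral channel subsetting, log10 transform, per-channel
    zero-mean normalization, bilinear spatial resizing, deterministic
    augmentation), an ENVI reader/writer, a synthetic transmittance-cube
    generator with a simulated annotation oracle, a deterministic
    nearest-centroid reference classifier, and annotation-budget learning
    curves comparing acquisition strategies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
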