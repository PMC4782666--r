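Package: dwisig
Title: Signal Intensity Gradient Analysis of Diffusion-Weighted MR Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the heterogeneity of brain-tumor regions on axial
    diffusion-weighted MR slices with the signal intensity gradient (SIG)
    technique. Tumor regions of interest are tiled into small subregions,
    each probed with the eight Robinson compass gradient kernels; the
    per-slice resultant SIGs (maximum response over tumor-side tiles,
    minimum response over mirrored contralateral tiles) are averaged into
    per-subject decisive SIGs and normalized into the relative SIG (RSIG)
    statistic that separates glioma-like from meningioma-like heterogeneity.
    Includes DICOM/BMP/PNG slice-stack input, a synthetic phantom generator
    with ground-truth tumor masks, cohort-level paired and Welch t-test
    reporting, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
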