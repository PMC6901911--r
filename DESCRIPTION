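Package: radplsc
Title: Paired-Modality MR Radiomics with Partial Least Squares Correlation
    and Neural-Network Lesion Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discriminates dominant intra-prostatic lesions from mirrored
    contralateral normal tissue on paired T2-weighted and apparent diffusion
    coefficient (ADC) MR volumes. Provides a synthetic paired-modality cohort
    generator with mono-exponential diffusion decay, ADC fitting by log-linear
    regression, NT-mean intensity harmonization, a 168-feature radiomics
    extractor (histogram, gray-level run-length, Laws, Stockwell, local binary
    pattern, wavelet, Gabor and co-occurrence families), two-block partial
    least squares correlation with bootstrap-ratio feature ranking and a
    permutation inertia test, a small back-propagation multilayer perceptron
    with leave-one-out and repeated-split validation, contour-robustness
    testing, and sliding-window lesion probability mapping with Dice
    evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    cluster,
    RNifti,
    jsonlite,
    yaml,
    digest,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
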