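Package: wmdamage
Title: Contrast-Weighted White Matter Damage Metric from Structural Brain MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.com>
Description: Quantifies white matter hyperintensity (WMH) burden on FLAIR or
    T2-weighted brain MRI as the proportion of WMH in the tissue where it can
    appear (brain tissue excluding the cortex), weighted by the relative
    image contrast of WMH with respect to normal-appearing white matter
    (NAWM). Includes the segmentation routes that produce the metric's
    inputs (red-green colour fusion with minimum-variance quantisation,
    multispectral Gaussian-mixture tissue clustering, and FLAIR histogram
    thresholding at mean + k standard deviations), aggregation of visual
    rating scales (Fazekas, Prins, total small vessel disease score),
    longitudinal change measures, agreement and association statistics
    (Bland-Altman, bootstrapped Spearman correlation, ANCOVA, paired tests),
    and a synthetic multi-sequence brain phantom generator with closed-form
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
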