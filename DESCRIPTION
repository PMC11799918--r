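Package: lvdose
Title: Dose-Reduction Limits for CT-Derived Left-Ventricular Function
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An objective-observer pipeline for studying how far CT
    radiation dose (tube current) can be reduced before left-ventricular
    functional metrics degrade. Synthetic truncated-ellipsoid LV phantoms
    with closed-form ground-truth metrics are imaged by a simulated
    parallel-beam CT, low-dose scans are emulated by projection-domain
    Poisson + Gaussian noise insertion, volumes are segmented (rule-based
    observer or a small residual 3D U-Net trained with a generalized Dice
    loss), reformatted into two-chamber, parasternal long-axis and
    short-axis views, and measured (ejection fraction, global longitudinal
    strain, circumferential strain, 16-spoke wall thickening). A study
    driver compares every low-dose result against the standard-dose result
    of the same case and locates the acceptable-dose threshold.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
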