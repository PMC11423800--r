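Package: samba
Title: Spiral Acquisition Matching-Based Quantitative T1 and T2 Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for rapid quantitative MRI
    relaxometry with a spiral acquisition and dictionary matching (SAMBA).
    Provides closed-form and recursive signal models for inversion-recovery
    Look-Locker and T2-preparation sequences, dictionary generation and
    voxel-wise matching for T1/T2 mapping, interleaved Archimedean spiral
    trajectory design with density compensation and Kaiser-Bessel gridding
    reconstruction, gold-standard least-squares spin-echo fitting, synthetic
    multi-tube digital phantoms with Rician noise, and the evaluation layer
    (ROI statistics, linear regression, Bland-Altman agreement, coefficient
    of variation repeatability, and scan-time-normalized efficiency).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    RNifti,
    jsonlite,
    yaml,
    withr,
    generics,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    class
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    optparse
Config/testthat/edition: 3
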