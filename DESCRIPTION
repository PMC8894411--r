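Package: femver
Title: Trigonometric Reconstruction of Femoral Component Version from
    Biplanar Orientation Angles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs the transverse-plane version of a femoral total hip
    arthroplasty component from its coronal and sagittal inclinations (and any
    permutation of the three orthogonal-plane angles) via closed-form
    tangent-product equations, backed by an explicit vector-geometry forward
    model of the prosthetic neck axis in scanner or mechanical-femoral
    anatomical frames.  Includes a model of the bias introduced by
    non-orthogonal biplanar imaging, a synthetic-cohort generator with
    truncated-normal orientation distributions and calibrated Gaussian
    measurement noise, agreement statistics (two-way absolute-agreement
    intraclass correlation with F-based confidence intervals, Bland-Altman
    bias and limits of agreement, median absolute differences), and an
    end-to-end validation-study pipeline with a small command-line interface.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
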