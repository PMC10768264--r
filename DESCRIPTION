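Package: ggnshape
Title: Shape Quantification of Lung Ground-Glass Nodules on CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the shape of segmented lung ground-glass nodules
    (GGN) from CT-derived binary masks: selects the maximal cross-section
    across the axial, coronal and sagittal orientations, measures the
    maximal area (MA), the longest diameter (LD) and its greatest
    perpendicular diameter (PD), and the two vertex angles of the
    quadrilateral spanned by the LD and PD chords, yielding the BiA/SmA
    angle-asymmetry ratio and the LD/PD elongation ratio. Includes the
    downstream cohort analysis used to separate precursor glandular
    lesions plus minimally invasive adenocarcinoma (PGL+MIA) from invasive
    adenocarcinoma (IAC): group comparisons, binary logistic regression
    with odds ratios, ROC curves with DeLong confidence intervals and
    Youden cut-offs, and a published predictive-probability equation.
    A synthetic bi-ellipse nodule generator with closed-form ground truth
    supports end-to-end validation without clinical data.
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
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    grDevices,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    png,
    pROC,
    tiff,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
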