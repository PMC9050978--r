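Package: ctrad
Title: CT Radiomic Heterogeneity Analysis for Lung Lesions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for quantifying lung-cancer heterogeneity from
    2-D CT slices. Generates synthetic lesion phantom cohorts with controllable
    shape, texture, repeat-scan noise and linked clinical outcomes; segments
    lesions by thresholding and morphological active contours (region- and
    edge-based); extracts a compact radiomic panel (circularity, variance,
    kurtosis, energy, GLCM cluster shade and maximum probability, GLRLM long-run
    high gray-level emphasis, a wavelet-approximation long-run emphasis, and
    lesion diameter); combines the panel into a 0-100 composite prognostic score
    with a random survival forest; and evaluates prognosis (Harrell's C,
    time-dependent AUC, Kaplan-Meier stratification, Cox hazard ratios),
    profile associations (Wilcoxon / Spearman differential expression), and
    measurement reproducibility (ICC, Bland-Altman).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    png,
    stats,
    survival,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
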