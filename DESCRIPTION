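Package: bap1scan
Title: Intratumor Heterogeneity of BAP-1 Immunohistochemistry in Uveal Melanoma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies intratumor heterogeneity of BAP-1 nuclear expression
    from per-cell immunohistochemistry detections in uveal melanoma sections.
    Classifies cells as BAP-1 positive or negative against a per-slide
    exemplar-calibrated threshold with nucleus-size filtering and
    exclusion-region masking, scans the tumor with 0.5 mm circular windows to
    locate hot spots, cold spots and scleral-margin minima, computes
    heterogeneity in percentage points and semi-ellipsoid tumor volume, screens
    eleven regression curve families, and calibrates prognostic cutoffs by ROC
    (Youden index) feeding Kaplan-Meier, univariate Cox and likelihood-ratio
    chi-square change comparisons of nested survival models. Includes a
    synthetic-data module generating tumor geometries, marked cell point
    patterns with planted spatial structure, and survival-linked cohorts so the
    whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    grDevices,
    jsonlite,
    pracma,
    stats,
    survival,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
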