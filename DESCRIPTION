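Package: quindorm
Title: Seed Dormancy Phenotyping from Germination Assays, Seed Scans and
    NIR Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Rule-based classification of primary seed dormancy strength in
    quinoa (Chenopodium quinoa) variety panels from hormone (ABA/GA)
    germination assays, including the after-ripening and scarification
    decision tree that separates embryo-imposed from seed-coat-imposed
    dormancy and flags viability concerns.  Companion stages cover the full
    phenotyping pipeline: germination statistics (arcsine transform, one-way
    ANOVA with Tukey all-pairwise comparisons and compact letter display),
    seed morphometrics from flatbed-scanner images (watershed segmentation,
    moment-ellipse axes, eccentricity, Crofton perimeter, solidity),
    near-infrared spectral quality control (calibration-range and
    Mahalanobis/chi-square outlier filters, dry-matter adjustment),
    factorial analysis of mixed data (FAMD) implemented from the weighted
    encoding up, and proportional-odds ordinal logistic regression fit by
    Newton-Raphson maximum likelihood.  A seeded synthetic-panel generator
    with known ground truth (dormancy classes, dose-response parameters,
    trait distributions, low-rank spectra, rendered seed scans) makes every
    stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    EBImage,
    png,
    yaml
Suggests:
    MASS,
    ggplot2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
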