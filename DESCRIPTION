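Package: otoshape
Title: Otolith Outline Morphometrics with Wavelet Descriptors and
    Constrained Ordination
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for population discrimination of fish stocks from
    otolith shape. Extracts closed outlines from grayscale otolith
    images, samples equally angle-spaced centroid-to-outline radii,
    decomposes them with an orthonormal periodized discrete wavelet
    transform, and carries the coefficients through the downstream
    statistics: intraclass-correlation profiles along the outline,
    ANCOVA-based coefficient filtering for length-by-population
    allometry, canonical analysis of principal coordinates with
    age-covariate adjustment, ANOVA-like permutation tests with
    a-priori contrasts, within-population variance by age group, and
    Mantel tests of isolation by distance against along-coast
    geographic distances. A synthetic outline generator with
    population-specific localized deformations along a coastal
    gradient supports calibration and end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    EBImage,
    geosphere
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    knitr,
    rmarkdown
biocViews: Software, StatisticalMethod, Visualization, Classification
Config/testthat/edition: 3
RoxygenNote: 7.3.3
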