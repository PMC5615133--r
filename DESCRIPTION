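Package: microcoda
Title: Compositional Data Analysis of Microbiome Count Tables Across Cohorts
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A unified compositional data-analysis toolkit for 16S rRNA OTU
    count tables compared across sample cohorts (for example age groups).
    Provides count-zero-multiplicative zero replacement, centered log-ratio
    (clr) transformation, Dirichlet Monte-Carlo posterior instances,
    compositional PCA biplots and Ward clustering on the Aitchison distance,
    expected standardized effect sizes for group pairs, the symmetric rho
    proportionality metric with threshold-graph clustering, PERMANOVA and
    beta-dispersion, Shannon diversity with read-depth diagnostics, and a
    Dirichlet-multinomial synthetic data generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan
Config/testthat/edition: 3
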