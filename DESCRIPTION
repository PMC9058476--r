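Package: confluentq
Title: Confluence Analysis of Atomic Charge Assignment Methods
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A standardized statistical framework for comparing methods that
    assign net atomic charges (NACs) to atoms in molecules and materials.
    Provides instant least squares fitting (ILSF), a reversible bivariate
    regression of standardized variables that simultaneously solves total
    least squares, orthogonal distance regression, and PCA regression;
    confluence metrics built on the average standardized variable and summed
    correlations; principal components analysis of the correlation matrix
    with power-iteration diagnostics; method ranking with spam-robustness and
    subset sensitivity analyses; integer running-sum consistency checking and
    physical-bounds validation of charge tables; point-charge electrostatic
    potential error evaluation on van der Waals shell grids; and a synthetic
    correlated-charge generator with known latent-factor ground truth.
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
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
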