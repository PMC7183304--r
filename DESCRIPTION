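Package: coralmse
Title: Sampling-Design Precision for Coral Assemblages via the
    Multivariate Pseudo Standard Error
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates the pseudo multivariate dissimilarity-based
    standard error (MultSE) of benthic community samples from
    photo-quadrat point annotations, with bias-corrected bootstrap
    percentile intervals per site. Simulates alternative hierarchical
    sampling designs (transects x quadrats x points per quadrat) by
    resampling re-annotated survey data, evaluates MultSE over a
    factorial design grid, and identifies the design that minimises it
    via linear regression on Box-Cox-transformed values. Includes
    principal coordinates analysis with signed-axis bookkeeping, a
    Dirichlet-multinomial generator of synthetic point-annotation
    datasets, and a reproducible config-driven pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils,
    tools,
    vegan,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
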