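Package: waxsboost
Title: Helical Structure Descriptors of RNA Duplexes from Solution X-Ray
    Scattering by Gradient-Boosted Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline that learns the mapping between solution
    small- and wide-angle X-ray scattering (SWAXS) profiles of 12-base-paired
    RNA duplexes and five helical structure descriptors: helical radius,
    twist, rise, major groove width and A-form fraction. Provides a
    coarse-grained duplex generator driven by helical parameters, a
    Debye-equation scattering calculator on a fixed momentum-transfer grid,
    a parametric solution-condition model with additive-offset
    buffer-subtraction correction, descriptor extraction from bead geometry,
    conformation-grouped dataset assembly for gradient-boosted tree
    regression and classification, feature-importance traces in q-space,
    and Monte-Carlo propagation of experimental errors through trained
    models via Gaussian resampling of noisy profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    glmnet,
    graphics,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
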