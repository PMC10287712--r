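Package: chillqy
Title: Chilling-Unit Modelling of Winter Cold Damage to Eucalyptus Leaf
    Quantum Yield
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts cold-stress damage to Eucalyptus globulus leaves from
    daily temperature records. Builds rolling-window chilling accumulation
    units (day counts or temperature deficits below a threshold) from daily
    maximum, minimum or average temperature, selects the logit-linear model
    of photosynthetic quantum yield (QY) with minimum AIC by exhaustive
    search over a threshold-by-window grid, constructs 95% confidence and
    prediction intervals on the QY scale, interpolates site-level climate
    suitability to a latitude/longitude grid with a support vector machine,
    and extrapolates long-term warming trends in annual minimum QY. Includes
    a synthetic climate and QY generator so the whole pipeline can be
    exercised and validated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    kernlab,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
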