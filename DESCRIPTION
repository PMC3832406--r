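Package: reefcast
Title: Scenario Analysis of Coral Reef Futures Under Multiple Local and Climatic Stressors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A stochastic difference-equation simulator of coral reef benthos
    (hard coral, epilithic algal communities, macroturf, macroalgae) and
    consumers (herbivorous fish, piscivorous fish, sea urchins) under
    nutrification-sedimentation, fishing and thermal bleaching forcings; a
    factorial Monte-Carlo scenario engine for management and climate
    scenarios; and the permutational multivariate statistics used to analyse
    simulated reef states (PERMANOVA with permutation of residuals under a
    reduced model, PERMDISP, canonical analysis of principal coordinates,
    non-metric multidimensional scaling, multivariate effect sizes and
    stressor-interaction classification), together with bleaching-recovery
    and time-to-collapse trajectory metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils,
    tools,
    MASS,
    vegan,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
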