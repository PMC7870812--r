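Package: cluesdm
Title: Integrated Land-Use Allocation and Species Distribution Modelling
    for Climate Impact Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale integrated assessment chain linking economy-driven
    land demand, CLUE-S style iterative land-use allocation, and
    presence-background species distribution models to separate direct
    (biophysical) from indirect (land-use mediated) climate-change impacts
    on species' ecologically suitable ranges. Includes a synthetic-data
    module generating spatially autocorrelated covariate fields, land-use
    maps with known multinomial-logistic ground truth, effort-biased
    species occurrences, pseudo-GCM climate ensembles and CGE-style sector
    demand trajectories, so that every stage of the pipeline can be
    exercised and validated against known truth without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
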