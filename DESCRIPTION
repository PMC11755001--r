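Package: demaxes
Title: Demographic Trade-Off Axes from Forest Census Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates species-level growth, survival and seed-to-seedling
    transition rates across ontogenetic size classes from repeated forest
    census data, and extracts the multivariate life-history axes that
    structure them. Trees are assigned to canopy layers with the perfect
    plasticity approximation, demographic rates are estimated with
    hierarchical Bayesian models that pool species within size classes,
    missing rates are imputed with a regularized iterative principal
    components algorithm, and the growth-survival and stature-recruitment
    trade-off axes are identified by permutation tests on eigenvalues and
    loadings. Post-hoc tools relate functional traits to the axes, compare
    ordinations between sites by Procrustes analysis, run an
    inverse-species-count weighted global PCA, and delineate core and full
    life-history hull areas. A synthetic multi-census forest generator with
    planted trade-off structure provides ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    coda,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    rjags,
    optparse
Config/testthat/edition: 3
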