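Package: isocompete
Title: Isotopic Niches, Competition Coefficients, and Community Stability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers trophic organization and local (Lyapunov) stability of a
    benthic invertebrate assemblage from specimen-level carbon and nitrogen
    stable-isotope data and litterbag census counts. Provides isotopic niche
    geometry (delta13C range and variance, convex-hull total area, standard
    ellipse areas with small-sample correction, hull and ellipse overlaps),
    a Bayesian stable-isotope mixing model with trophic enrichment factors,
    Levins diet-overlap competition coefficients, isotope-distance
    competition coefficients from intra- vs interspecific specimen
    distances, Lotka-Volterra carrying capacities, community and Jacobian
    matrices with inverse-Jacobian net-effect analysis, perturbed and
    randomized stability nulls, and a synthetic-community generator for a
    seagrass habitat-degradation gradient.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    deSolve
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
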