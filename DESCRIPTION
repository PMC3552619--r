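Package: micromix
Title: Individual-Based Models of Pattern Formation in Microbial Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Individual-based lattice simulators of vertical pattern formation
    in surface-attached microbial communities, together with the statistics
    used to quantify those patterns. Two simulators are provided: a fitness
    model in which growth rates follow from basal fitness, pairwise ecological
    interaction coefficients and local crowding, and a diffusion model in
    which growth follows explicitly simulated nutrient release, diffusion and
    Michaelis-Menten uptake through the community and the agarose below it.
    Pattern statistics include digitization of two-channel vertical
    cross-sections, the intermixing index and the characteristic vertical
    patch size. Mean-field steady-state theory for the six pairwise ecological
    interaction classes, an interaction-length-scale calculator, random
    multi-species interaction-network experiments and synthetic test fixtures
    complete the toolkit.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    png,
    tiff,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
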