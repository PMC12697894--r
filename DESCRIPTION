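Package: firedrive
Title: Spatial Modeling of Homing Suppression Gene Drives in Fire Ants
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Individual-colony, spatially explicit simulation of CRISPR homing
    suppression gene drives in invasive fire ants (Solenopsis invicta).
    Colonies are agents with a queen genome and a stored mate genome; the model
    covers monogyne and polygyne social forms governed by the SB/Sb supergene,
    greenbeard culling of SB/SB alates, haplodiploid inheritance with drive
    conversion and germline/embryo resistance, five enhanced drive variants,
    logistic colony growth, density-dependent competition with a linear-decline
    kernel, native-ant competitors and invasion fronts.  A companion
    deterministic discrete-generation panmictic haplodiploid model computes
    equilibrium genetic load, suppression thresholds and generation times.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
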