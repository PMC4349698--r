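Package: molardiet
Title: Dietary Inference from Molar Shearing and Occlusal Topography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs diet categories (folivore, frugivore, hard-object
    feeder) of platyrrhine primates from first-molar occlusal morphology.
    Implements mesh-based dental topographic indices (Relief Index and
    Occlusal Relief from triangle meshes of molar crowns), shearing quotients
    as percentage residuals from a frugivore-calibrated phylogenetic
    generalized least-squares regression of summed crest lengths on molar
    length, Pagel's lambda phylogenetic-signal estimation, simulation-based
    phylogenetic ANOVA with Brownian-motion nulls, non-parametric group
    comparisons with Bonferroni correction, and equal-prior linear
    discriminant classification with leave-one-out cross-validation. A
    synthetic-data generator produces trees, species means under Brownian
    motion with diet-group offsets, specimen tables with within-species
    noise, and parametric cusp-on-base tooth meshes with known geometry.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    grDevices,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    phytools,
    MASS
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
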