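Package: nestmech
Title: Structural Mechanics of Edible-Nest Swiftlet Nests from Volumetric Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative workflow for the structural analysis of edible-nest
    swiftlet (Aerodramus fuciphagus) nests and similar thin-walled,
    additively built biological structures. Provides a seeded synthetic nest
    phantom with ground-truth material and closed-pore masks; readers and
    writers for volumetric image stacks (TIFF, BMP, MetaImage) with explicit
    voxel-spacing metadata; a micro-CT style segmentation pipeline (Gaussian
    smoothing, grayscale thresholding, largest-component retention, linear
    resampling, closed-pore extraction with a small-pore fill rule);
    morphometric descriptors (volume, exposed-face surface area, slice
    profiles, pore orientation by inertia tensors); reduction of tensile
    force-displacement records to engineering stress-strain curves with
    modulus, peak-stress and failure extraction; and a voxel-hexahedral
    linear-elastic finite-element solver with gravity body forces, pinned
    constraints, distributed nodal loads and maximum-principal-stress
    recovery, plus bird/egg loading scenarios with region statistics and
    safety factors against the material's tensile fracture strength.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
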