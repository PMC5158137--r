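Package: cytomech
Title: Microtubule Network Morphometry and AFM Cell Elasticity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of the microtubule cytoskeleton and of
    cell mechanics in cultured cells. From reconstructed superresolution
    images of immunostained microtubule networks it measures network
    density, crossing (branch-point) density and the local axial alignment
    of filaments via angle doubling, using top-hat enhancement, fixed
    thresholding, topology-preserving thinning and a rotating linear
    structuring element. From atomic force microscopy approach curves
    acquired with a spherical bead indenter it estimates the cell Young's
    modulus by fitting the Sneddon rigid-sphere contact model at fixed
    indentation depths, with joint contact-point estimation. A synthetic
    data module generates ground-truthed filament images and forward
    modelled force curves so every stage of the pipeline is testable.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3), methods
Imports:
    stats,
    utils,
    tools,
    EBImage,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'hertz-fit.R'
    'io.R'
    'morphology-utils.R'
    'morphometry.R'
    'orientation.R'
    'pipeline.R'
    'rank-test.R'
    'sneddon.R'
    'synthetic-curve.R'
    'synthetic-network.R'
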