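Package: omsretina
Title: Simulation and Analysis of an Object-Motion-Sensitive Retinal Circuit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study object motion sensitivity in the inner retina: a
    visual stimulus engine (area-response spots, split fields, counterphase
    annuli, differential texture motion, moving bars, drifting gratings,
    Gaussian white noise), a rectified-subunit linear-nonlinear circuit
    simulator of glutamatergic VG3 amacrine cells and W3 ganglion cells with
    TTX and VGluT3-knockout switches, and the matching analysis stack:
    epoch amplitudes and conductance extraction, F1/F2 harmonic analysis,
    motion/size/speed/direction tuning, disc-integrated Difference-of-Gaussians
    receptive-field fits, ON/OFF temporal-filter recovery from white noise via
    response-weighted ensembles and principal components, and anatomical
    statistics (density recovery profiles of soma mosaics, convex-hull neurite
    territories, and synaptic-apposition fractions with Monte Carlo nulls).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    Matrix,
    minpack.lm,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'anatomy.R'
    'circuit.R'
    'filters.R'
    'io.R'
    'metrics.R'
    'omsretina-package.R'
    'pipeline.R'
    'receptive_field.R'
    'stimuli.R'
    'utils.R'
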