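Package: gastruflow
Title: Multi-Scale Analysis of Cell Tracks and Tissue Flows in Zebrafish Gastrulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pan-embryo analysis of zebrafish gastrulation from
    single-cell tracking data and light-sheet image stacks: a synthetic
    embryo simulator with ground truth, embryo-centric spherical
    coordinates and Mercator projection, transmission-stack two-sphere
    fitting with shell masking and a concatenated-intensity storage
    format, nucleus detection and iterative-closest-point time
    registration, channel subtraction into germ layers, straightness-index
    and radial track statistics, gridded tissue flow fields with
    epiboly/convergence decomposition, circular correlation across
    layers, density-weighted streamlines, inter-layer residual motion,
    force-directed edge bundling and viewer exports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite,
    tiff,
    EBImage
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
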