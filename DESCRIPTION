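Package: wormmri
Title: Motion-Predictive MR Imaging Simulation for Freely Moving C. elegans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation platform for studying how center-line motion
    prediction rescues magnetic-resonance image quality when the imaged
    organism moves freely during acquisition. Generates synthetic
    bright-field videos of a crawling Caenorhabditis elegans with exact
    ground-truth poses and a library of 64x64 cross-sectional slice
    phantoms; detects the worm in each frame, builds a normalized
    center-line coordinate system (head s = 0, tail s = 1), and predicts
    future positions of arbitrary points of interest via s_c = s - v * dk;
    simulates line-by-line gradient-echo Cartesian k-space acquisition
    with the gradient center either following the predictor, held fixed,
    or guided by the ground truth; and scores reconstructions against the
    true slice with the structural similarity measure, including the
    body-position, resolution-ratio and prediction-horizon simulation
    paradigms and an imageability taxonomy based on motion, prediction
    and repetition timescales.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    stats,
    utils,
    png,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
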