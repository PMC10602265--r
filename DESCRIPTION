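Package: scanpathsim
Title: Mechanistic Simulation and Evaluation of Scanpaths on Dynamic Scenes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates human scanpaths (saccade timing and targeting, smooth
    pursuit, fixational jitter) on dynamic scenes with a modular drift-diffusion
    race between potential saccade targets. Targets are either pixel locations
    (space-based selection) or segmented objects (object-based selection), with
    gaze-dependent visual sensitivity, an anisotropic centre bias, and
    space- or object-bound inhibition of return. Includes a synthetic-scene
    generator (moving labelled objects, co-located feature blobs, consistent
    optical flow), HDF5 scene archives, scanpath-evaluation statistics
    (Kolmogorov-Smirnov distribution distances, functional foveation
    categories, sequential turning-angle and return diagnostics), synthetic
    human-like reference event tables, and an evolutionary (rank-selection,
    Gaussian-mutation) parameter-fitting protocol.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    rhdf5,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
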