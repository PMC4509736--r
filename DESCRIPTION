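Package: photonsim
Title: Photon-Counting Simulation of TIRF and Confocal Fluorescence
    Microscopy Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Forward simulator for fluorescence microscopy that turns
    fluorophore coordinate trajectories into digital TIRF and laser-scanning
    confocal images whose pixel values are traceable photon counts. Covers
    the full chain: evanescent-field or focused Gaussian-beam illumination,
    per-fluorophore photon-budget arithmetic, Born-Wolf point-spread-function
    image formation with finite-region normalization, confocal pinhole
    integration, and a Monte Carlo detector model (shot noise, quantum
    efficiency, dark current, electron-multiplying gain with excess noise,
    readout noise, binning, and A/D quantization). Includes Brownian-dynamics
    generators for ground-truth samples (surface plate, solution box,
    hemispherical cell) and a mean-squared-displacement diffusion estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
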