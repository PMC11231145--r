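Package: fpmfa
Title: Fourier Ptychographic Microscopy Simulation and Fractal Assay of Diatom Phase Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates Fourier ptychographic microscopy (FPM) acquisitions of
    diatom-like phase scenes, reconstructs super-resolved quantitative
    phase-contrast maps by iterative object and pupil retrieval, and derives
    copper-stress descriptors from the reconstructed maps: multi-scale
    lacunarity (the ratio of global to local gliding-box lacunarity), range
    GLCM entropy, exponential and cubic dose-calibration curves, and a
    two-step classifier that assigns a measured field of view to one of seven
    copper dose intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    yaml,
    jsonlite,
    minpack.lm,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
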