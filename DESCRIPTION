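Package: axisim
Title: Axial-Interference Speckle Illumination Microscopy: Simulation and
    Super-Resolution Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates coherent speckle illumination modified by a
    back-reflecting mirror (axial standing-wave interference), renders
    synthetic speckle-illuminated fluorescence acquisitions with an EMCCD
    noise model, and reconstructs super-resolved volumes by temporal
    cumulant analysis (SOFI/SACD style) with dynamic-speckle-illumination
    weighting, Richardson-Lucy deconvolution with a Fourier-ring-correlation
    stopping rule, and brightness linearization. Includes reference-free
    resolution estimation by image decorrelation analysis, FWHM and
    resolution-isotropy reporting, SSIM frame-budget validation, and simple
    particle tracking, together with a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
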