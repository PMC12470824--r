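Package: ccxfct
Title: Bilateral Compton-Camera X-Ray Fluorescence Tomography Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and image reconstruction for X-ray fluorescence
    computed tomography (XFCT) with bilateral two-layer Compton cameras.
    Provides a seeded list-mode Monte Carlo event generator for a
    gold-nanoparticle cylinder phantom, effective-Compton-event screening,
    dynamic cone/attenuation system-matrix assembly, list-mode MLEM with
    total-variation (Split Bregman) regularization, 3D post-processing by
    anisotropic TV diffusion and wavelet-domain soft thresholding,
    isosurface extraction, and evaluation metrics (angular resolution
    measure, energy resolution, contrast- and signal-to-noise ratios).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    Matrix,
    Rcpp,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
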