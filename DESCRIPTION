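Package: muellerpol
Title: Mueller Matrix Polarimetry Simulation and Analysis for Ring-Shaped
    Tissue Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward simulation and analysis of transmission Mueller matrix
    polarimetry of engineered ring-shaped tissue constructs. Provides a
    digital twin of a 48-frame polarization state generator / analyzer
    acquisition, eigenvalue calibration of the instrument matrices,
    pixel-wise Mueller matrix reconstruction by pseudo-inversion,
    Lu-Chipman polar decomposition and Mueller matrix transformation
    parameter maps, median-absolute-deviation tissue masking, ROI and
    radial line-profile statistics with a non-parametric test battery,
    and 3D fiber-orientation analysis of second-harmonic-generation-like
    volumes including spherical variance. Synthetic ring phantoms,
    calibration reference acquisitions and fiber volumes with known
    ground truth are generated in code.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    tiff,
    yaml,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
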