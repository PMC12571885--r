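Package: mdirspec
Title: Active-Learning Interatomic Potentials and Molecular-Dynamics Infrared Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale workflow for predicting gas-phase infrared spectra of
    small H/C/N/O molecules from machine-learned force fields. An analytic
    bonded force field with a point-charge dipole surface acts as the labelling
    oracle; committee (query-by-ensemble) active learning grows a training set
    for kernel-regression surrogate potentials; Langevin molecular dynamics
    driven by committee-averaged forces yields dipole trajectories; infrared
    spectra follow from the Fourier transform of the dipole time-derivative
    autocorrelation function. Includes normal-mode analysis and sampling,
    clustering-based test-set construction, extended-XYZ input/output, and
    Pearson/Wasserstein spectral similarity metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
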