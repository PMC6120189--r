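Package: rho1kin
Title: Gating Kinetics and Quantification Pipeline for rho1 GABA-A Receptors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Six-state Markov (Q-matrix) gating model for homomeric rho1
    GABA-A receptors with preactivated, open and desensitized states;
    deterministic occupancy simulation through concentration-jump
    protocols via piecewise matrix-exponential propagation; Hill-equation
    fits for activation and inhibition concentration-response data;
    constrained bi-exponential deactivation fits with amplitude-weighted
    time constants; joint multi-start calibration of the wild-type rate
    set against published mutant summary statistics under fixed
    perturbation rules; synthetic data generators (noisy traces,
    Hill-shaped datasets, two-channel cell images with ground-truth
    masks) and membrane-fluorescence ROI quantification (background
    corrected DeltaROI).
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    Matrix,
    jsonlite,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
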