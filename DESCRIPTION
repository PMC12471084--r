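Package: prostreg
Title: Cross-Modal Deformable Registration of MRI and TRUS Prostate Volumes
Version: 0.1.0
Authors@R: person("prostreg", "developers", role = c("aut", "cre"),
    email = "prostreg@example.org")
Description: Deformable cross-modal registration of paired 3D prostate
    volumes (MRI-like and TRUS-like), built around a dual-encoder
    convolutional network with enhanced cross-modal channel attention,
    diffeomorphic stationary-velocity-field integration by scaling and
    squaring, pseudo-temporal LSTM refinement of the deformation field
    along the depth axis, and a composite mutual-information, Dice and
    gradient-smoothness objective. Includes a synthetic phantom generator
    with known ground-truth deformations, NIfTI input/output, registration
    quality metrics (DSC, TRE, robust variants, Jacobian folding), a
    CPU training loop with reverse-mode automatic differentiation, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
NeedsCompilation: yes
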