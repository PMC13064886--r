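Package: vfpinn
Title: Physics-Informed Neural Networks for In Vacuo Vocal Fold Eigenmodes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Computes in vacuo eigenmodes and eigenfrequencies of a two-layer
    body-cover vocal fold model. Provides a finite-element modal solver for
    the transversely isotropic body-cover prism (trilinear hexahedra, sparse
    generalized eigensolver) used to generate reference modal datasets over a
    grid of material configurations, and a physics-informed neural network
    (SiLU material encoder feeding a sinusoidal representation network) that
    learns per-mode displacement fields by minimizing a composite loss built
    from the Navier-Cauchy residual, boundary and interface conditions, a
    Rayleigh-quotient eigenvalue penalty, and a cosine mode-shape penalty.
    Includes collocation sampling with layer-volume-consistent quadrature
    weights, modal assurance criterion mode matching, evaluation reports, and
    VTK/CSV export of mode shapes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
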