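Package: perturbspec
Title: Geometric Spectral Analysis of Low-Rank Matrix and Operator Perturbations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing the spectrum of a real matrix or operator
    subject to a rank-one or rank-two perturbation M + rho1*f1*g1' + rho2*f2*g2'.
    The characteristic function det(M + rho1 f1 g1' + rho2 f2 g2' - lambda I)
    is assembled as D(lambda) + rho1 P1(lambda) + rho2 P2(lambda) +
    rho1 rho2 Q(lambda), from which constant-eigenvalue curves, the envelope
    (double-eigenvalue) curve, Hopf curves, singular bifurcation pieces and
    triple-eigenvalue points in the (rho1, rho2) parameter plane are computed,
    and the plane is partitioned into regions of constant eigenvalue
    configuration.  Includes model builders for a brainstem-cerebellum neural
    integrator network (discrete and continuum forms) with mode-gain and
    impulse-response diagnostics, and elliptic-function machinery for the
    stability index of front solutions of a mass-conserving nonlocal
    Allen-Cahn equation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
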