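Package: phragmoFEM
Title: Finite-Element Models of Cephalopod Phragmocone Mechanics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parametric finite-element modelling of chambered cephalopod
    shells (phragmocones). Generates lobate and Koch-fractal suture lines,
    spans them with minimum-curvature septal surfaces, assembles capped
    double-walled cylindrical shells with conformal tetrahedral meshes,
    solves linear isotropic elasticity under external hydrostatic pressure,
    and post-processes cylindrical stress components, principal stresses,
    line probes, region statistics and pressure-to-depth equivalences for
    comparative experiments on septal complexity, spacing and shell
    thickness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
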