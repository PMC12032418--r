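Package: fetalsound
Title: Modelling In-Utero Exposure to Airborne Sound
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts the transmission of external airborne sound into the
    pregnant uterus. Provides tissue acoustic material models (power-law and
    loss-tangent attenuation, complex wavenumbers), generators for nested
    triangulated phantoms at anatomical scale with Gmsh and STL input/output,
    an analytical layered-sphere solution for plane-wave scattering, a dense
    boundary-element solver (multi-domain PMCHWT formulation) for the
    Helmholtz transmission problem on nested surfaces, twelfth-octave
    frequency-sweep exposure metrics (spatial-RMS and maximum sound pressure
    levels, barycentre pressure), and least-squares FIR auralization of the
    predicted in-utero frequency response.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
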