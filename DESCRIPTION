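Package: phantomlight
Title: Light Transport and Wavefront Shaping in Volume-Scattering Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Forward and inverse light-transport calculations for slab-shaped
    volume-scattering phantoms with well-defined optical properties. Provides
    a P_N (spherical-harmonic) solution of the radiative transfer equation in
    slab geometry with Henyey-Greenstein scattering and exact Fresnel boundary
    radiance (angular, partial-angular and ballistic transmittance into a
    detection numerical aperture), a photon-transport Monte Carlo oracle in
    compiled code, a look-up-table inversion of integrating-sphere observables
    (total hemispherical transmittance and reflectance) to the effective
    scattering and absorption coefficients, and a random-phasor simulator of
    feedback wavefront shaping with the stepwise sequential algorithm,
    compared against the theoretical phase-only enhancement law.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    pracma,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
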