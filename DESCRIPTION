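Package: besselff
Title: Neural-Network Force Fields Built on Spherical Bessel Descriptors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Differentiable neural-network interatomic potentials for dense
    molecular and ionic systems. Atomic environments are encoded as
    element-pair spherical Bessel descriptors (an orthonormal radial basis
    derived from spherical Bessel functions contracted with Legendre
    polynomials into a rotationally invariant power spectrum), which feed a
    multilayer perceptron that predicts additive atomic energies. Exact
    analytic forces are obtained through a vector-Jacobian-product operator
    for the descriptors, enabling training directly on reference forces with
    a log-cosh loss, the Adam optimizer and a one-cycle learning-rate
    schedule. The package also provides subsampling-aggregation ensembles for
    extrapolation detection, an optional charge-equilibration long-range
    term with smeared Coulomb interactions, a velocity-Verlet/Nose-Hoover
    molecular-dynamics engine, velocity-autocorrelation and Green-Kubo
    diffusion analyses, bond-scan diagnostics, extended-XYZ input/output and
    a synthetic-data generator based on an analytic reference potential.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
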