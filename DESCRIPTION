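Package: halodose
Title: Double-Gaussian Pencil-Beam Dose Engine for Scanned Proton Beams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A CPU reference implementation of a pencil-beam dose calculation
    engine for spot-scanned proton therapy using a double-Gaussian lateral
    beam model. The low-dose nuclear halo is carried by a second, wider
    Gaussian whose fraction u and large-angle width sigma_LA are supplied
    either by the analytic Soukup parameterization or by a direct
    nonlinear-least-squares fit of two Gaussians to radial dose profiles.
    The halo dose is computed on a coarser beam's-eye-view lattice with one
    halo pencil beam per physical spot, making its kernel-superposition cost
    a small fraction of the primary's. Includes synthetic ground-truth
    generators (pseudo-Monte-Carlo radial profiles, analytic Bragg curves,
    water and slab phantoms), water-equivalent path-length raytracing,
    scattering-model recalibration, and a 3D gamma-index comparison tool.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    pracma,
    jsonlite,
    mgcv
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
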