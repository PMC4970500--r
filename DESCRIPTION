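Package: fxisim
Title: Forward Simulation of Flash X-Ray Imaging Diffraction Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A forward simulator for flash X-ray imaging (FXI) with X-ray
    free-electron lasers. Given a photon source, one or more sample particle
    models (analytic spheres and spheroids, voxelized refractive-index maps,
    or atomic coordinate sets) and a pixel-array detector, it computes
    far-field coherent scattering amplitudes on the Ewald sphere under the
    first-order Born approximation and converts them to expected and
    Poisson-sampled photon counts per pixel. Includes element scattering
    factors and optical-medium refractive-index conversions, stochastic
    per-shot particle ensembles with random orientations and positions,
    CXI/HDF5 output, and a command-line entry point driven by an INI-style
    configuration file.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    bio3d,
    rhdf5,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
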