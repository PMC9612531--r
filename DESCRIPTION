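Package: fusbone
Title: Focused Ultrasound Propagation Through Flat Bone and Surrogate
    Attenuation/Refraction Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates low-intensity focused ultrasound (LIFU) propagation
    through a flat homogeneous bone layer with a k-space pseudospectral
    time-domain acoustic solver (heterogeneous density and sound speed,
    stationary power-law absorption, split-field perfectly matched layer),
    voxelizes focused bowl transducers, and tabulates the attenuation and
    refraction of the focal point relative to water-only propagation over a
    five-dimensional parameter space (carrier frequency, bone thickness,
    trajectory angle, focal depth, transducer diameter).  The resulting
    surrogate tensors are queried by multilinear interpolation and rendered
    as 2-D parameter-space maps.  Closed-form references (O'Neil focused-bowl
    field, Rayleigh-Sommerfeld integral, three-medium slab transmission) and
    convergence procedures are included for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
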