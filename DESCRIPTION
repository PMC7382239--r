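Package: mtconfine
Title: Self-Organizing Cortical Microtubule Arrays in Confined Geometries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Three-dimensional stochastic simulation of cortical microtubule
    networks confined inside well geometries (boxes, spheres, cylinders,
    triangular prisms), with dynamic instability, angle-dependent bundling,
    collision-induced catastrophe and katanin-style severing at microtubule
    crossovers. Includes quantification of network order on opposite domain
    faces via the weighted 2D nematic order parameter (S2, ThetaS2), an
    intensity-gradient nematic-tensor estimate of anisotropy for grayscale
    images, synthetic image rendering, circular two-sample Kuiper and
    Kolmogorov-Smirnov tests with permutation options, bootstrap sample-size
    assessment, legacy VTK polyline input/output, and an experiment runner for
    shape-by-severing parameter sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
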