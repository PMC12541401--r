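Package: oxydrop
Title: Oxygen-Driven Self-Organization of Confined Bacterial Droplets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coupled oxygen-bacteria reaction-diffusion model of a quasi-2D
    confined droplet of aerotactic swimming bacteria. Dissolved oxygen
    diffuses in from the air-liquid interface (Robin mass-transfer boundary
    condition) and is consumed by the cells via Michaelis-Menten kinetics;
    cell motility (active diffusivity and aerotactic drift) and uptake shut
    down below a critical oxygen level through smooth tanh switching. The
    package provides a conservative finite-volume solver for the axisymmetric
    dimensionless system, observable extraction (anoxic-core radius, motile
    annulus width, total oxygen content, kymographs), three-way regime
    classification (aerobic, transient anoxia, permanent anoxia), state-diagram
    sweeps with bisection boundary location and boundary-form fitting, the
    oxygen penetration-length scaling analysis, and a synthetic-microscopy
    phantom generator (Beer-Lambert bright-field, Ru(dpp) oxygen fluorescence,
    Henry's law) for end-to-end validation of the quantification pipeline.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    ggplot2,
    rlang,
    generics,
    minpack.lm,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
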