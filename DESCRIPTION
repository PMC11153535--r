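Package: ivoctsim
Title: In Silico Intravascular Optical Coherence Tomography with Saline Flushing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates the complete intravascular optical coherence tomography
    (IVOCT) acquisition cycle in an axisymmetric vessel-catheter geometry:
    pulsatile blood inflow, normal-saline flushing through a guiding catheter
    (solved with a finite-volume incompressible flow and erythrocyte transport
    model), a Lambert-Beer attenuation/backscatter optical forward model that
    turns haematocrit fields into A-lines and grayscale images, and
    image-quality scoring (residual irradiance ratio at the vessel wall,
    clear-image-frame counting, clear imaging length, and a composite quality
    indicator) together with saline dosage accounting. Ships continuous and
    intermittent injection schedules and a comparison experiment between them.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    png,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
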