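Package: discflow
Title: Centrifugal Perfusion Physics and Protocol Planning for Disc-Shaped
    Organ-on-Chip Platforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models pump- and tubing-free medium perfusion on rotating,
    disc-shaped organ-on-chip platforms. Implements rotation kinematics
    (angular velocity, centrifugal acceleration, relative centrifugal force,
    effective gravity), the centrifugal and hydrostatic pressure budget,
    Hagen-Poiseuille flow through rectangular microchannels with the
    aspect-ratio correction, and a capillary burst-valve threshold model for
    flow versus rotation speed. Provides an error-weighted fitter that
    estimates the burst pressure from flow-rate measurement campaigns with
    parametric-bootstrap uncertainties, a seeded synthetic campaign generator
    for parameter-recovery studies, and spin-protocol planners for centrifugal
    cell loading and perfusion with cell-budget arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
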