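Package: lumibr
Title: Bioturbation Imaging and Integrated Biomarker Responses for
    Bivalve Heat-Wave Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing mesocosm heat-wave experiments on
    sediment-dwelling bivalves. Implements fluorescent sediment-profile
    imaging (f-SPI): merging of aquarium side photographs, pixel-scale
    calibration, HSV segmentation of fluorescent tracer particles
    (luminophores), sediment-water interface tracing, and particle
    reworking metrics (mean, median and maximum mixed depth, surface
    boundary roughness). Post-processes subcellular biomarker panels by
    baseline percent-change normalization, derives cellular energy
    allocation (CEA = Ea/Ec), and integrates biomarkers into the
    Integrated Biological Response index version 2 (IBRv2) with star-plot
    decompositions. Provides the minimal-adequate-model workflow used for
    such designs: generalized least squares with per-stratum variance
    structures selected by REML AIC, backward fixed-effect selection by
    ML likelihood-ratio tests, and REML re-expression. A seeded
    synthetic-data generator emulates the full 28-aquarium native vs
    invasive clam design so every stage is testable end to end.
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
    nlme,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
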