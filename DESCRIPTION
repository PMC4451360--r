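Package: instmfa
Title: Isotopically Non-Stationary 13C Metabolic Flux Analysis for
    Photoautotrophic Central Carbon Metabolism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates absolute carbon fluxes and metabolite pool sizes in a
    simplified model of the Calvin-Benson cycle, photorespiration and the
    starch, sucrose and trehalose synthesis pathways from time courses of
    unlabeled metabolite fractions recorded after a switch to 13CO2.
    Implements the mass-state-zero cumomer (EMU) balance equations driven by
    two-exponential ribulose-1,5-bisphosphate input models, an
    11-dimensional flux-mode parameterization (4 elementary flux modes plus
    7 exchange cycles), variance-weighted least-squares fitting of three
    pool-size treatment scenarios with multistart derivative-free
    optimization, Monte-Carlo confidence intervals, and a
    perturb-and-reoptimize sensitivity analysis of flux estimates with
    respect to individual metabolic contents. Includes a synthetic-data
    generator emulating the experimental design (7 sampling times from 5 s
    to 60 min, 14 observed metabolites, compartment mixing and inactive
    fractions) for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
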