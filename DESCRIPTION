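Package: laserlesion
Title: Laser-Induced Cell Damage Analysis from Fluorescence and Thermal Imaging
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of in vitro laser damage experiments on
    pigmented retinal pigment epithelium (RPE) cell monolayers. Builds binary
    damage masks from live/dead (calcein/ethidium) fluorescence images using
    gradient-weighted robust automatic threshold selection (RATS) with
    morphological cleaning, registers the masks onto calibrated infrared
    thermal video to extract threshold temperatures at the boundary of cell
    death, fits probit dose-response models with Fieller fiducial limits and
    quality gates, detects deterministic (crossover-free) thresholds, and
    implements Bunsen-Roscoe irradiance reciprocity tests, exact-binomial
    damage-frequency intervals, and concurrent-exposure interaction
    classification. Ships a synthetic-data generator with known ground truth
    (flat-top beams, linear irradiance-temperature response, photothermal and
    photochemical lesion phenotypes, probit outcome draws) so the whole
    pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    igraph,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
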