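Package: synhomeo
Title: Simulation and Quantal Analysis of Presynaptic Homeostatic Plasticity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying presynaptic homeostatic plasticity (PHP) at
    the Drosophila neuromuscular junction and for simulating the data such
    experiments produce. Includes generators for miniature-event traces,
    60 Hz depression trains from a vesicle depletion-replenishment model,
    electrophysiology screen tables and two-channel puncta geometries;
    Clements-Bekkers template-matching event detection; quantal content, PHP
    normalization and readily-releasable-pool estimation by cumulative-EPSC
    back-extrapolation; screen hit calling by ANOVA with Tukey correction,
    assumption-gated two-group tests and power-based sample sizing;
    Monte-Carlo nearest-neighbor-distance colocalization tests and
    block-scramble correlation nulls; and threshold-based puncta morphometry.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    mgcv,
    car
Suggests:
    testthat (>= 3.0.0),
    tiff,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
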