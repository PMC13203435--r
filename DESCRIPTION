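Package: aquatrack
Title: Multi-Object Tracking and Behavioral Rhythm Analysis for Camouflaged Aquatic Animals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tracking-by-detection for camouflaged, nonlinearly moving
    underwater animals such as giant salamanders. Provides overlap-based
    association kernels (IoU, GIoU, DIoU, CIoU and a biologically constrained
    BIOU with an elongation prior), a dual-branch Transformer trajectory
    predictor trained with a physiological velocity-cap loss, a three-stage
    cascaded matcher with dormant-track reactivation, rule-based behavior
    classification with day/night rhythm summaries, a seeded synthetic
    scenario generator, and CLEAR-MOT evaluation (MOTA, IDF1, identity
    switches, fragmentations). Reads and writes MOTChallenge-style detection,
    ground-truth and result files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
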