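Package: dyadimaging
Title: Behavior and Interaction Imaging for Mother-Infant Dyads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying early mother-infant interaction from
    multimodal recordings: bootstrap particle-filter tracking of a colored
    wristband in video frames, kinematic / pause / curvature descriptors of
    2D hand trajectories, speech-turn-taking segmentation with dyadic
    synchrony features from vocalization timelines, a two-stream (cepstral +
    prosodic) Gaussian-mixture classifier for infant-directed speech
    (motherese), and leave-one-out decision-stump classification of
    developmental outcome groups after PCA reduction. Includes a synthetic
    dyad generator so every stage of the pipeline can be exercised and
    validated without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
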