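Package: marlseg
Title: Multi-Agent Reinforcement-Learning Segmentation of Ultrasound Lesions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Edge-driven multi-agent deep reinforcement learning for
    delineating lesion boundaries in 2-D grayscale ultrasound images. Virtual
    agents live on the edge map, follow offset trajectories generated around a
    coarse attention mask, and are rewarded by Gestalt-law criteria
    (continuity, proximity, closure, density). Policies are trained with
    proximal policy optimization and generalized advantage estimation under a
    curriculum ordered by an edge-map complexity taxonomy. Includes a
    synthetic ultrasound-like phantom generator with known ground truth,
    contour and area quality metrics (Hausdorff variants, Dice, Jaccard), and
    an end-to-end segmentation pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
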