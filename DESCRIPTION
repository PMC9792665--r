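Package: trunksyn
Title: Synergy-Based Estimation of Trunk Muscle Activations During Gait
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates unmeasured trunk muscle activations during walking by
    combining time-varying muscle synergy activations, extracted from leg
    muscle activations with non-negative matrix factorization, with trunk
    synergy-vector weights found by convex optimization so that rigid-tendon
    Hill-type musculotendon moments about the three lumbosacral degrees of
    freedom track inverse-dynamics moments. Includes gait-cycle segmentation
    and OpenSim storage file I/O, strength personalization from anatomical
    cross-sectional areas, fiber-length tuning, optimization-based muscle-set
    reduction, a per-frame static-optimization baseline, evaluation metrics
    (moment RMSE and electromechanical-delay-swept Pearson correlation), and
    a synthetic gait-data generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    pracma,
    signal,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
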