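Package: jugglekit
Title: Decomposing Three-Ball Juggling Skill into Sequencing, Prediction,
    and Accuracy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for decomposing early three-ball cascade juggling skill
    into three kinematic components: Sequencing (Hilbert-transform
    instantaneous-phase scoring of the 120-degree ball phase relationship),
    Prediction (catch success under apex-locked visual occlusion), and
    Accuracy (95% probability-ellipsoid volume of hand-centred catch
    positions). Includes a synthetic-data generator for cascade and
    occlusion kinematics with full ground truth, a frame-wise ball tracker
    and throw/catch event labeller, monotone and robust-z index transforms,
    and self-implemented Gamma-Log and Normal-Identity generalized linear
    models with Wald inference, likelihood-based fit metrics, day-wise
    evaluation and leave-one-subject-out cross-validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    MASS,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
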