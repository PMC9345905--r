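Package: gripsynth
Title: Precision-Grip Synthesis by Minimization of Muscle Effort
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Synthesis of biomechanically feasible precision-grip postures of
    a musculoskeletal human hand model. A 21-segment kinematic chain with 37
    hand muscles and constant moment arms is combined with object-side grasp
    mechanics (grasp matrix, twelve-sided linearized friction cones, soft
    fingertip contact pairs) to pose grip synthesis as a convex quadratic
    program minimizing the sum of squared muscle activations subject to
    object force/moment equilibrium, Coulomb friction and the muscle-to-
    fingertip force balance. Hand posture for candidate fingertip contact
    positions is obtained by penalized inverse kinematics, and the contact
    positions themselves are optimized by a covariance matrix adaptation
    evolution strategy (CMA-ES). Also provides the measured-versus-simulated
    fingertip force comparison arithmetic (per-condition differences and
    accuracy/precision summaries) used to validate such models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    quadprog,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
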