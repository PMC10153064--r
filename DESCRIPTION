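Package: reacharm
Title: Planar Arm Reaching Simulations with Hill-Type Muscle Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Forward-dynamic simulation of planar three-joint arm reaching
    driven by six Hill-type muscles, with interchangeable muscle models
    (instantaneous, first-order and third-order activation dynamics; constant
    or force-length-velocity modulated strength) and a predictive
    proportional-derivative feedback controller with an approximate inverse
    muscle model. Includes minimum-jerk reach planning, tracking and
    stabilisation error metrics, agonist-antagonist co-contraction analysis,
    twitch characterization of activation models, and mixed-integer genetic
    optimization of feedback gains and prediction time.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    withr
Config/testthat/edition: 3
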