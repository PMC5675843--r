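Package: aecvision
Title: Active Efficient Coding Simulator for Joint Saccade and Vergence Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates an active binocular vision system in which a perceptual
    representation (a generative adaptive-subspace self-organizing map over
    binocular image patches), a reinforcement-learned vergence policy and a
    binocular-saliency-driven saccade generator develop jointly on synthetic
    stereo scenes. Includes the scene generator with ground-truth disparity,
    the GASSOM encoder, a natural actor-critic vergence learner, global and
    local self-information saliency maps with inhibition of return, and the
    full set of evaluation protocols (vergence RMSE, fixation entropy,
    disparity-tuning curves and V-fits, expected disparity differences, and
    within-fixation reconstruction-error decrease).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tibble,
    minpack.lm,
    png,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
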