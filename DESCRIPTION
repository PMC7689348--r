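Package: navpace
Title: Gait and Gaze Analysis of Spatial Learning During Real-World Navigation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for cognitive-motor interference during spatial
    learning in a real environment. Turns raw motion-capture marker series and
    mobile eye-tracking samples into per-trial walking speed (median over
    straight-ahead steps), trajectory efficiency and goal-fixation proportion,
    and from those derives the learning criterion trial, adaptation indices,
    and the percent change in walking speed between the first and reference
    trials, with an assumption-gated two-group statistical layer (Student's t
    or Mann-Whitney U after Shapiro-Wilk and Levene checks, Pearson
    correlations, Bonferroni correction). Includes gait event detection from
    heel-marker kinematics, dispersion-threshold fixation detection, gaze-ray
    intersection with a 3D room model, and a synthetic-cohort generator with
    ground truth so every stage is testable without human recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    car,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
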