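Package: kneefdk
Title: Force-Dependent Kinematics Simulation of the Tibiofemoral Joint
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Desk-scale musculoskeletal simulation of the human knee:
    piecewise quadratic/linear ligament bundle mechanics, elastic-foundation
    contact between triangulated cartilage and meniscus surfaces,
    cubic-polynomial static-optimization muscle recruitment, and quasi-static
    resolution of the secondary tibiofemoral and patellofemoral degrees of
    freedom by force-dependent kinematics (FDK). Produces total, medial and
    lateral tibiofemoral contact force curves over activity cycles, together
    with the curve-validation metrics (RMSE, R-squared, Sprague-Geers
    combined error) customary in gait biomechanics. Ships seeded generators
    for parametric knee geometry and five daily-activity motion and
    ground-reaction profiles so the whole pipeline runs without measured data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
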