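Package: mdlt
Title: Multiple Decrement Life Tables and Elimination-of-Cause Analysis
    for Insect Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds abridged multiple decrement life tables for stem-dwelling
    insect cohorts from destructive dissection records, partitions stage
    mortality among competing causes (parasitism, plant defense, cannibalism,
    pathogens, unknown factors), and performs elimination-of-cause analysis:
    net probabilities of death in the absence of competing causes via the
    quadratic solution, joint mortality of cause subsets, and irreplaceable
    mortality.  Includes a stage-structured competing-risks cohort simulator
    that emulates a replicated field sampling design (weekly stem
    cross-sections plus pre- and post-flight stub collections) with known
    ground truth for estimator validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
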