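Package: patchPo
Title: Single-Channel Open Probability Estimation from Patch-Clamp and
    Whole-Cell Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating the open probability of epithelial
    sodium channels (ENaC) and similar constitutively gating ion channels
    from on-cell patch-clamp and two-electrode voltage-clamp (TEVC)
    recordings. Implements amplitude-histogram construction, fitting of a
    sum of Gaussian components whose means are constrained to equidistant
    multiples of the unitary current, conversion of component weights to
    level occupation probabilities, binomial occupancy modelling with
    channel-count scanning under two anchoring conventions, and whole-cell
    estimators based on amiloride-sensitive current fractions (protease
    fold change and the MTSET degenerin-site relative-activity estimator).
    A two-state Markov gating simulator generates patch and whole-cell
    traces with known ground truth so that every stage of the pipeline is
    testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
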