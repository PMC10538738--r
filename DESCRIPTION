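Package: musono
Title: Quantitative Muscle Ultrasound Normative Cutoffs and Diagnostic Rules
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for diagnostic analysis of quantitative neuromuscular
    ultrasound. Builds age- and sex-stratified 5th-percentile normative
    cutoffs for relaxed and contracted muscle thickness from a healthy
    control cohort, applies multi-muscle reduced-thickness decision rules
    and fasciculation-count criteria to patient records, computes the
    biceps-EDB proximal-distal thickness differential, and evaluates
    diagnostic accuracy (per-group sensitivity, specificity, and ROC
    area under the curve via binary-threshold, empirical rank, and
    binormal estimators). Includes a seeded synthetic cohort generator
    that emulates the group-wise distributions of a neuromuscular clinic
    population (controls, myopathy, polyneuropathy, amyotrophic lateral
    sclerosis, spinal muscular atrophy) and a command-line interface
    wiring the full pipeline together.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
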