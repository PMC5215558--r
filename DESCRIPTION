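Package: calfnet
Title: Proximity-Logger Social Networks and Weaning Stress in Pair-Housed Calves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing dairy-calf social structure from spatial
    proximity-logger contact streams, together with the pen-rearing
    production and weaning-stress statistics that accompany such studies.
    Includes logger record parsing and filtering, per-logger recording-bias
    correction, weekly weighted association networks, network stability
    (Mantel/QAP node-label permutation tests), social differentiation with
    permutation nulls, a Bayesian dyadic regression of association strength
    on familiarity and treatment with multi-membership calf random effects
    (Gibbs sampler, DIC model comparison), bootstrap-permutation ANOVA for
    treatment contrasts, specific growth rate and health-score summaries
    with two-stage sharpened FDR correction, and a synthetic-data generator
    that emulates a staggered-entry pair-housing experiment end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
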