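Package: replicheck
Title: Replication Assessment for Highly Cited Clinical Effect Estimates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing whether published clinical effect estimates
    were replicated by later studies. Given pairs of (original, replication)
    effect estimates -- odds, risk, hazard or incidence rate ratios, or
    objective response rates -- the package scores replication success under
    several criteria (statistical significance in the same direction,
    confidence interval overlap, point-estimate containment), quantifies
    effect-size inflation on the log scale with coining and publication-order
    adjustments, re-estimates meta-analytic effects after removing an index
    study (DerSimonian-Laird random effects with Mantel-Haenszel common-effect
    weighting), and compares predictors of replicability with exact tests.
    A bundled dataset transcribes 24 pairs of highly cited clinical studies
    (2004-2018) and their replications; a synthetic pair generator supports
    calibration experiments such as winner's-curse simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), metafor, optparse, withr, knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
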