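Package: pvror
Title: Case/Non-Case Disproportionality Analysis for Pharmacovigilance Signal Detection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for case/non-case disproportionality studies in spontaneous
    adverse-event reporting databases. Builds analysis cohorts from individual
    case safety report (ICSR) line listings, labels composite MedDRA-style
    events and ATC-class drug exposures, and estimates crude and
    confounder-adjusted reporting odds ratios (r-OR) with Woolf and Wald 95%
    confidence intervals and a lower-bound signal rule. Includes positive and
    negative control validation, age-band subgroup, sensitivity and
    concomitant-event analyses, collinearity diagnostics, and a synthetic ICSR
    generator with known ground-truth effects and injected confounding for
    end-to-end validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
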