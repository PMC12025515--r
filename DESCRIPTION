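Package: sigrev
Title: Signature-Reversal Drug Repurposing and Co-Prescription Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for transcription-driven drug repurposing and its
    pharmacoepidemiological follow-up. Builds per-gene signed-Z differential
    expression profiles from normalized expression matrices by ordinary
    least squares with covariates, combines profiles across independent
    studies into composite disease meta-profiles by Stouffer's summed-Z
    rule, scores query signatures against compound-profile libraries with
    library-standardized correlation Z scores and positive/negative ranks,
    and tests top-gene sign reversal against an exact binomial null. A
    companion module constructs binary-exposure cohorts from longitudinal
    prescription registries (ATC-coded dispensing events) and quantifies
    drug co-prescription associations by crude 2x2 odds ratios and
    Newton-Raphson maximum-likelihood logistic regression, including a
    sensitivity grid over prescription-count thresholds, age restrictions
    and sex strata. Seeded synthetic-data generators emulate multi-study
    case/control expression, planted-correlation compound libraries and
    confounded prescription registries so every stage is testable end to
    end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
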