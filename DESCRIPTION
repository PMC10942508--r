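Package: evidenceyield
Title: Evidence Yield of Calibrated PP3/BP4 Computational Predictions in Rare-Disease Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Counts rare missense variants per proband by calibrated ACMG/AMP
    PP3/BP4 computational-evidence strength. Ingests per-proband VCFs with
    VEP-style consequence annotations, applies genotype-quality and allele-
    frequency filters, maps metapredictor scores (BayesDel, MutPred2, REVEL,
    VEST4) to evidence-strength categories via calibrated interval thresholds,
    and aggregates cohort yield tables with bootstrap confidence intervals and
    exact binomial comparisons between mode-of-inheritance strata. Includes
    the Bayesian point-based adaptation of the ACMG/AMP classification
    framework (posterior probability of pathogenicity from summed evidence
    points) and a synthetic-cohort generator that emulates the statistical
    structure of a rare-disease genome cohort so the full pipeline is testable
    without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
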