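Package: srsddi
Title: Drug-Drug Interaction Signal Mining in Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R: person("Hubei", "Pharmacovigilance Tools", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Two-detector screening for drug-drug interaction (DDI) safety
    signals in spontaneous adverse-drug-reaction (ADR) report databases.
    Candidate (drug1, drug2, adverse event) triples are scored with
    association-rule metrics (support, confidence, lift, conviction) and with
    the Omega shrinkage disproportionality measure computed from a 4x2
    contingency table; a triple is flagged only when it passes both detectors.
    Includes report ingestion and term standardization, inclusion filtering,
    sex- and age-stratified screening, descriptive summaries, and a synthetic
    spontaneous-report generator with injected interaction effects for
    end-to-end validation and parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
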